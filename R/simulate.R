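#' Simulate a random reference genome
#'
#' Uniform-random ACGT contigs, byte-identical under a fixed seed. Used as
#' the reference strain's genome in simulated F1 hybrid designs.
#'
#' @param lengths named integer vector of contig lengths (>= 1000).
#' @param seed integer seed.
#' @return a `DNAStringSet`.
#' @export
simulate_reference <- function(lengths, seed = 1L) {
  stopifnot(length(lengths) >= 1L, all(lengths >= 1000L))
  if (is.null(names(lengths)))
    names(lengths) <- paste0("chrS", seq_along(lengths))
  with_seed(seed, {
    seqs <- Biostrings::DNAStringSet(vapply(lengths, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
      ""))
    names(seqs) <- names(lengths)
    seqs
  })
}

#' Simulate strain variants against a reference
#'
#' Draws SNPs and short indels along each contig at the configured
#' per-base rates (defaults emulate the divergence of distant inbred mouse
#' strains: one SNP per 150 bp, one indel per 1,500 bp, indels up to
#' `max_indel` bp). Records are primitive and non-overlapping by
#' construction, so the emitted VCF round-trips losslessly through
#' [load_variants()].
#'
#' @param ref a `DNAStringSet`.
#' @param snp_rate per-base SNP probability (default 1/150).
#' @param indel_rate per-base indel probability (default 1/1500).
#' @param max_indel maximum inserted/deleted length in bp (default 6).
#' @param seed integer seed.
#' @return a `VariantSet` (the ground truth).
#' @export
simulate_strain_variants <- function(ref, snp_rate = 1 / 150,
                                     indel_rate = 1 / 1500, max_indel = 6L,
                                     seed = 1L) {
  stopifnot(snp_rate >= 0, snp_rate <= 1, indel_rate >= 0, indel_rate <= 1)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    recs <- list()
    for (chrom in names(ref)) {
      seq <- as.character(ref[[chrom]])
      len <- nchar(seq)
      snp_pos <- which(stats::runif(len) < snp_rate)
      ind_pos <- which(stats::runif(len) < indel_rate)
      cand <- rbind(
        if (length(snp_pos))
          data.frame(pos = snp_pos, is_indel = FALSE),
        if (length(ind_pos))
          data.frame(pos = ind_pos, is_indel = TRUE))
      if (is.null(cand) || nrow(cand) == 0L) next
      cand <- cand[order(cand$pos, cand$is_indel), , drop = FALSE]
      ins_flag <- stats::runif(nrow(cand)) < 0.5
      ilen <- sample.int(max_indel, nrow(cand), replace = TRUE)
      last_end <- -1L
      for (i in seq_len(nrow(cand))) {
        p <- cand$pos[i]
        if (p <= last_end) next
        anchor <- substr(seq, p, p)
        if (!cand$is_indel[i]) {
          alt <- sample(setdiff(bases, anchor), 1L)
          recs[[length(recs) + 1L]] <- data.frame(
            chrom = chrom, pos = p, ref = anchor, alt = alt)
          last_end <- p
        } else if (ins_flag[i]) {
          ins <- paste(sample(bases, ilen[i], replace = TRUE),
                       collapse = "")
          recs[[length(recs) + 1L]] <- data.frame(
            chrom = chrom, pos = p, ref = anchor,
            alt = paste0(anchor, ins))
          last_end <- p
        } else {
          if (p + ilen[i] > len) next
          recs[[length(recs) + 1L]] <- data.frame(
            chrom = chrom, pos = p,
            ref = substr(seq, p, p + ilen[i]), alt = anchor)
          last_end <- p + ilen[i]
        }
      }
    }
    if (length(recs) == 0L)
      return(variant_set(data.frame(chrom = character(), pos = integer(),
                                    ref = character(), alt = character())))
    variant_set(do.call(rbind, recs))
  })
}

#' Write a VariantSet as a plain-text VCF 4.2 file
#'
#' @param variants a `VariantSet`.
#' @param path output path.
#' @param ref optional `DNAStringSet` supplying `##contig` header lines.
#' @export
write_vcf <- function(variants, path, ref = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(ref))
             paste0("##contig=<ID=", names(ref), ",length=",
                    vapply(ref, length, 0L), ">"),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  body <- if (nrow(variants) > 0L)
    paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
          ".", "PASS", ".", sep = "\t") else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate allelic paired-end reads on a diploid genome
#'
#' Draws paired fragments from gene models with a programmed per-gene
#' maternal fraction and emits them as alignments on the diploid genome
#' (contigs `<chrom>_<strain>`), so the classification pipeline can be
#' exercised without an external aligner. Each fragment's haplotype is the
#' ground truth. Fragments that overlap at least one strain variant get
#' MAPQ 42; fragments from variant-free sequence are identical on both
#' haplotypes and get MAPQ 0, emulating the ambiguous mappings an aligner
#' reports on a diploid genome. Read strands follow the fr-firststrand
#' library convention for the gene's strand.
#'
#' @param ref reference `DNAStringSet`.
#' @param variants a `VariantSet` for the variant strain.
#' @param genes data.frame with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), `maternal_fraction`,
#'   `n_fragments`.
#' @param cross a [cross_orientation()].
#' @param strain_a,strain_b reference / variant strain names.
#' @param read_length read length in bp (default 100).
#' @param insert_size fragment length in bp (default 300).
#' @param error_rate per-base sequencing error probability (default 0).
#' @param seed integer seed.
#' @return list with `alignments` (SAM-style table on diploid contigs),
#'   `truth` (one row per read: `qname`, `mate`, `strain`, `parent`,
#'   `gene`), `pseudo`, `liftmaps` (named per-strain list; strain A is
#'   `NULL` identity), and `diploid` (the diploid `DNAStringSet`).
#' @export
simulate_allelic_reads <- function(ref, variants, genes, cross,
                                   strain_a = "B6", strain_b = "JF1",
                                   read_length = 100L, insert_size = 300L,
                                   error_rate = 0, seed = 1L) {
  pg <- build_pseudogenome(ref, variants)
  diploid <- build_diploid_genome(ref, pg$seq, strain_a, strain_b)
  liftmaps <- stats::setNames(list(NULL, pg$liftmap), c(strain_a, strain_b))
  vstart0 <- variants$pos - 1L
  vend0 <- variant_footprint_end(variants$pos, variants$ref)  # 1-based incl
  aln <- list(); truth <- list()
  with_seed(seed, {
    for (g in seq_len(nrow(genes))) {
      gn <- genes[g, ]
      if (gn$start < 0L || gn$end > length(ref[[gn$chrom]]))
        stop("gene ", gn$name, " outside contig ", gn$chrom)
      mat_strain <- cross$maternal_strain
      for (f in seq_len(gn$n_fragments)) {
        is_mat <- stats::runif(1) < gn$maternal_fraction
        strain <- if (is_mat) mat_strain else
          setdiff(c(strain_a, strain_b), mat_strain)
        hapseq <- if (strain == strain_a) ref[[gn$chrom]] else
          pg$seq[[gn$chrom]]
        # pick the fragment on the haplotype's own coordinates
        if (strain == strain_a) {
          lo <- gn$start; hi <- gn$end
        } else {
          lo <- ref_to_pseudo(pg$liftmap, gn$chrom, gn$start)
          hi <- ref_to_pseudo(pg$liftmap, gn$chrom, gn$end - 1L)
          if (is.na(lo)) lo <- 0L
          if (is.na(hi)) hi <- length(hapseq) - 1L
          hi <- hi + 1L
        }
        span <- hi - lo
        ins <- min(insert_size, span)
        fs <- lo + sample.int(max(span - ins, 0L) + 1L, 1L) - 1L
        fe <- fs + ins
        # ref-coordinate footprint decides the MAPQ ambiguity surrogate
        if (strain == strain_a) {
          rs <- fs; re <- fe
        } else {
          li <- lift_interval(pg$liftmap, gn$chrom, fs, fe)
          rs <- li$start; re <- li$end
        }
        sel <- variants$chrom == gn$chrom & vstart0 < re & vend0 > rs
        mapq <- if (any(sel)) 42L else 0L
        rl <- min(read_length, ins)
        left <- c(fs, fs + rl)
        right <- c(fe - rl, fe)
        # fr-firststrand: read2 carries the transcribed strand
        if (gn$strand == "+") {
          r1 <- list(iv = right, flag = 83L)   # paired,proper,rev,read1
          r2 <- list(iv = left, flag = 163L)   # paired,proper,mrev,read2
        } else {
          r1 <- list(iv = left, flag = 99L)
          r2 <- list(iv = right, flag = 147L)
        }
        qname <- sprintf("%s_f%06d", gn$name, length(truth) %/% 2L + 1L)
        for (mate in list(c(1, r1), c(2, r2))) {
          mi <- mate[[1]]; rec <- mate[-1]
          iv <- rec$iv
          sq <- as.character(Biostrings::subseq(hapseq, iv[1] + 1L, iv[2]))
          if (error_rate > 0) sq <- mutate_seq(sq, error_rate)
          aln[[length(aln) + 1L]] <- data.frame(
            qname = qname, flag = rec$flag,
            rname = paste0(gn$chrom, "_", strain),
            start = iv[1], end = iv[2],
            strand = if (bitwAnd(rec$flag, 0x10L) > 0L) "-" else "+",
            mapq = mapq, cigar = paste0(iv[2] - iv[1], "M"),
            seq = sq, qual = strrep("I", iv[2] - iv[1]),
            stringsAsFactors = FALSE)
          truth[[length(truth) + 1L]] <- data.frame(
            qname = qname, mate = mi, strain = strain,
            parent = if (strain == mat_strain) "maternal" else "paternal",
            gene = gn$name, stringsAsFactors = FALSE)
        }
      }
    }
  })
  list(alignments = do.call(rbind, aln), truth = do.call(rbind, truth),
       pseudo = pg$seq, liftmaps = liftmaps, diploid = diploid)
}

mutate_seq <- function(sq, rate) {
  ch <- strsplit(sq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Simulate an allelic 4C-seq experiment
#'
#' Draws interacting fragends per allele from a distance-decay contact
#' model, `P(fragend) proportional to distance^(-alpha) * multiplier`,
#' where allele-specific loop anchors get a per-allele enrichment
#' multiplier. Each read pair consists of a viewpoint mate synthesized
#' with the correct parental base at the viewpoint SNP and an interacting
#' mate whose alignment begins exactly at the drawn fragend (minus-strand
#' reads end there instead). An optional fraction of off-grid reads is
#' shifted off the fragend, to exercise the exactness filter. The two
#' bait-fragment fragends are excluded from the draw.
#'
#' @param ref reference `DNAStringSet` (one contig used).
#' @param chrom contig carrying bait and viewpoint.
#' @param bait_pos 0-based bait position.
#' @param vp a [viewpoint_spec()].
#' @param alpha distance-decay exponent (default 1).
#' @param anchors data.frame with `pos` (0-based fragend position; must be
#'   a fragend, otherwise a hard error), `maternal_mult`, `paternal_mult`,
#'   and optionally `n_fragends` (anchor width in consecutive fragends
#'   starting at `pos`, default 8): a loop anchor is a contiguous run of
#'   restriction fragments, not a single cut site.
#' @param n_reads informative pairs per allele per replicate (default 5000).
#' @param replicates number of paired replicates (default 2).
#' @param read_length interacting-mate read length (default 100).
#' @param frac_offgrid fraction of extra reads placed off the fragend grid
#'   (default 0).
#' @param site enzyme site (default `"GATC"`).
#' @param seed integer seed.
#' @return list with `pairs` (viewpoint-mate table for
#'   [demultiplex_viewpoint_pairs()]), `interacting` (interacting-mate
#'   alignment table in reference coordinates, without allele labels),
#'   `truth` (`qname`, `allele`, `fragend`, `replicate`, `on_grid`),
#'   `fragmap`, and `vp_seqs` (the two parental viewpoint sequences).
#' @export
simulate_4c_experiment <- function(ref, chrom, bait_pos, vp, alpha = 1,
                                   anchors = NULL, n_reads = 5000L,
                                   replicates = 2L, read_length = 100L,
                                   frac_offgrid = 0, site = "GATC",
                                   seed = 1L) {
  fragmap <- digest_genome(ref, site)
  len <- fragmap$seqlengths[[chrom]]
  grid <- fragmap$fragends[[chrom]]
  bf <- bait_fragends(fragmap, chrom, bait_pos)
  grid <- setdiff(grid, bf)
  w0 <- pmax(abs(grid - bait_pos), 1)^(-alpha)
  mult <- function(allele) {
    w <- w0
    if (!is.null(anchors) && nrow(anchors) > 0L) {
      for (a in seq_len(nrow(anchors))) {
        i <- which(grid == anchors$pos[a])
        if (length(i) != 1L)
          stop("anchor at ", anchors$pos[a], " is not a fragend")
        nf <- if (is.null(anchors$n_fragends)) 8L else anchors$n_fragends[a]
        run <- i:min(i + nf - 1L, length(grid))
        w[run] <- w[run] * anchors[[paste0(allele, "_mult")]][a]
      }
    }
    w / sum(w)
  }
  p_mat <- mult("maternal"); p_pat <- mult("paternal")
  vp_base <- c(maternal = vp$snp_maternal, paternal = vp$snp_paternal)
  vp_seq0 <- as.character(Biostrings::subseq(ref[[chrom]], vp$start + 1L,
                                             vp$end))
  vp_seqs <- vapply(vp_base, function(b) {
    s <- vp_seq0
    substr(s, vp$snp_pos - vp$start, vp$snp_pos - vp$start) <- b
    s
  }, "")
  pairs <- list(); inter <- list(); truth <- list()
  with_seed(seed, {
    for (rep_i in seq_len(replicates)) {
      for (allele in c("maternal", "paternal")) {
        pr <- if (allele == "maternal") p_mat else p_pat
        n_off <- round(n_reads * frac_offgrid)
        fe_idx <- sample.int(length(grid), n_reads + n_off, replace = TRUE,
                             prob = pr)
        fe <- grid[fe_idx]
        on_grid <- rep(TRUE, length(fe))
        if (n_off > 0L) {
          off_i <- seq.int(n_reads + 1L, n_reads + n_off)
          fe[off_i] <- pmin(fe[off_i] + sample.int(9L, n_off, replace = TRUE),
                            len - read_length)
          on_grid[off_i] <- FALSE
        }
        # strand: fragends at the contig edges force a side
        plus_ok <- fe < len
        minus_ok <- fe > 0L
        use_plus <- ifelse(plus_ok & minus_ok,
                           stats::runif(length(fe)) < 0.5, plus_ok)
        st <- ifelse(use_plus, fe, pmax(fe - read_length, 0L))
        en <- ifelse(use_plus, pmin(fe + read_length, len), fe)
        qn <- sprintf("r%d_%s_%06d", rep_i, substr(allele, 1, 3),
                      seq_along(fe))
        pairs[[length(pairs) + 1L]] <- data.frame(
          qname = qn, vp_chrom = vp$chrom, vp_start = vp$start,
          vp_end = vp$end, vp_mapq = 42L,
          vp_seq = vp_seqs[[allele]], replicate = rep_i,
          stringsAsFactors = FALSE)
        inter[[length(inter) + 1L]] <- data.frame(
          qname = qn, chrom = chrom, start = st, end = en,
          strand = ifelse(use_plus, "+", "-"), mapq = 42L,
          replicate = rep_i, stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          qname = qn, allele = allele, fragend = grid[fe_idx],
          replicate = rep_i, on_grid = on_grid, stringsAsFactors = FALSE)
      }
    }
  })
  list(pairs = do.call(rbind, pairs), interacting = do.call(rbind, inter),
       truth = do.call(rbind, truth), fragmap = fragmap, vp_seqs = vp_seqs)
}

#' Write simulated 4C pairs as FASTQ files
#'
#' Emits the viewpoint mates as R1 and interacting-mate sequences
#' (extracted from the reference at their simulated alignment) as R2, for
#' users who want to run a real aligner on simulated data.
#'
#' @param sim output of [simulate_4c_experiment()].
#' @param ref the reference `DNAStringSet` used in the simulation.
#' @param r1_path,r2_path output FASTQ paths.
#' @export
write_fourc_fastq <- function(sim, ref, r1_path, r2_path) {
  fq <- function(qname, seq, path) {
    writeLines(as.vector(rbind(paste0("@", qname), seq, "+",
                               strrep("I", nchar(seq)))), path)
  }
  fq(sim$pairs$qname, sim$pairs$vp_seq, r1_path)
  it <- sim$interacting
  sq <- as.character(Biostrings::extractAt(
    ref[[it$chrom[1]]], IRanges::IRanges(it$start + 1L, it$end)))
  rc <- it$strand == "-"
  sq[rc] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sq[rc])))
  fq(it$qname, sq, r2_path)
  invisible(c(r1_path, r2_path))
}
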