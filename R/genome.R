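#' N-mask a reference at strain SNP positions
#'
#' Returns a copy of the reference in which every SNP position from
#' `variants` is replaced by `N`. Indel records are ignored: masking is a
#' SNP-only device to remove mapping bias, whereas indels are handled by the
#' diploid genome and the lift map. Sequence lengths are unchanged.
#'
#' @param ref a `DNAStringSet` (multi-record FASTA already loaded, e.g. via
#'   [Biostrings::readDNAStringSet()]).
#' @param variants a `VariantSet`; its `ref` alleles must match `ref`.
#' @return a `DNAStringSet` of identical lengths with SNP positions masked.
#' @export
mask_reference <- function(ref, variants) {
  snps <- variants[variants$kind == "SNP", , drop = FALSE]
  check_ref_alleles(ref, as.data.frame(snps))
  out <- ref
  for (chrom in unique(snps$chrom)) {
    pos <- snps$pos[snps$chrom == chrom]
    out[[chrom]] <- Biostrings::replaceLetterAt(
      out[[chrom]], pos, rep.int("N", length(pos)))
  }
  out
}

#' Build a strain pseudogenome and its lift map
#'
#' Applies SNPs, insertions and deletions from `variants` to the reference
#' to reconstruct the variant strain's genome, and builds an indel-aware
#' [LiftMap] from pseudogenome coordinates back to reference coordinates.
#' With an empty variant set the output equals the reference and the lift
#' map is the identity.
#'
#' The lift map is block-wise: `MATCH` blocks map runs of bases one-to-one
#' (SNPs do not break blocks, since substitution preserves coordinates);
#' `INSERTED` blocks cover strain-specific insertions and carry a single
#' reference anchor, the 0-based position of the last reference base at or
#' left of the insertion (-1 for an insertion at the contig start).
#'
#' @inheritParams mask_reference
#' @return list with elements `seq` (a `DNAStringSet`) and `liftmap`
#'   (a `LiftMap`).
#' @export
build_pseudogenome <- function(ref, variants) {
  check_ref_alleles(ref, as.data.frame(variants))
  seqs <- Biostrings::DNAStringSet(lapply(names(ref), function(chrom) {
    v <- variants[variants$chrom == chrom, , drop = FALSE]
    apply_variants_seq(ref[[chrom]], v)
  }))
  names(seqs) <- names(ref)
  blocks <- lapply(names(ref), function(chrom) {
    v <- variants[variants$chrom == chrom & variants$kind != "SNP", ,
                  drop = FALSE]
    build_blocks(length(ref[[chrom]]), v)
  })
  names(blocks) <- names(ref)
  lm <- structure(list(blocks = blocks), class = "LiftMap")
  list(seq = seqs, liftmap = lm)
}

# One replaceAt call using original reference coordinates applies all
# variants at once: SNP -> substitute, INS -> zero-width insert after the
# anchor base, DEL -> delete the bases after the anchor.
apply_variants_seq <- function(seq, v) {
  if (nrow(v) == 0L) return(seq)
  at <- vector("list", nrow(v)); val <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    if (v$kind[i] == "SNP") {
      at[[i]] <- IRanges::IRanges(v$pos[i], v$pos[i]); val[i] <- v$alt[i]
    } else if (v$kind[i] == "INS") {
      at[[i]] <- IRanges::IRanges(start = v$pos[i] + 1L, width = 0L)
      val[i] <- substr(v$alt[i], 2L, nchar(v$alt[i]))
    } else { # DEL: remove the bases after the anchor base
      at[[i]] <- IRanges::IRanges(v$pos[i] + 1L,
                                  variant_footprint_end(v$pos[i], v$ref[i]))
      val[i] <- ""
    }
  }
  Biostrings::replaceAt(seq, do.call(c, at), val)
}

# Walk indels (sorted, non-overlapping) along one chromosome and emit the
# 0-based half-open block table. All coordinates here are 0-based.
build_blocks <- function(ref_len, indels) {
  blocks <- list()
  ref_at <- 0L; pseudo_at <- 0L
  emit_match <- function(ref_to) {
    if (ref_to > ref_at) {
      w <- ref_to - ref_at
      blocks[[length(blocks) + 1L]] <<- data.frame(
        pseudo_start = pseudo_at, pseudo_end = pseudo_at + w,
        ref_start = ref_at, ref_end = ref_to, kind = "MATCH")
      pseudo_at <<- pseudo_at + w; ref_at <<- ref_to
    }
  }
  if (nrow(indels) > 0L) {
    for (i in seq_len(nrow(indels))) {
      anchor_end0 <- indels$pos[i]        # 0-based end of anchor base + 1
      if (indels$kind[i] == "INS") {
        ins_len <- nchar(indels$alt[i]) - 1L
        emit_match(anchor_end0)
        blocks[[length(blocks) + 1L]] <- data.frame(
          pseudo_start = pseudo_at, pseudo_end = pseudo_at + ins_len,
          ref_start = anchor_end0 - 1L, ref_end = anchor_end0 - 1L,
          kind = "INSERTED")
        pseudo_at <- pseudo_at + ins_len
      } else { # DEL
        del_len <- nchar(indels$ref[i]) - 1L
        emit_match(anchor_end0)
        ref_at <- ref_at + del_len
      }
    }
  }
  emit_match(ref_len)
  if (length(blocks) == 0L) {
    return(data.frame(pseudo_start = integer(), pseudo_end = integer(),
                      ref_start = integer(), ref_end = integer(),
                      kind = character()))
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Identity lift map for a reference-strain haplotype
#'
#' @param ref a `DNAStringSet`.
#' @return a `LiftMap` with one MATCH block per chromosome.
#' @export
identity_liftmap <- function(ref) {
  blocks <- lapply(names(ref), function(chrom) {
    n <- length(ref[[chrom]])
    data.frame(pseudo_start = 0L, pseudo_end = n,
               ref_start = 0L, ref_end = n, kind = "MATCH")
  })
  names(blocks) <- names(ref)
  structure(list(blocks = blocks), class = "LiftMap")
}

#' @export
print.LiftMap <- function(x, ...) {
  nb <- vapply(x$blocks, nrow, 0L)
  cat("LiftMap over", length(x$blocks), "chromosome(s);",
      sum(nb), "blocks\n")
  invisible(x)
}

#' Lift a pseudogenome interval to reference coordinates
#'
#' Maps a 0-based half-open pseudogenome interval to the smallest reference
#' interval covering the images of all its MATCH bases. Flags report when
#' the query touched inserted (strain-specific) sequence and when it spanned
#' a deletion (its MATCH images are non-adjacent on the reference). A query
#' wholly inside an inserted block has no MATCH image: it returns the
#' zero-length interval at the insertion's reference anchor with
#' `insertion_only = TRUE`.
#'
#' @param liftmap a `LiftMap`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open query interval on the pseudogenome.
#' @return list with `start`, `end` (0-based half-open reference interval),
#'   and logical flags `insertion_only`, `touches_insertion`,
#'   `spans_deletion`.
#' @export
lift_interval <- function(liftmap, chrom, start, end) {
  b <- liftmap$blocks[[chrom]]
  if (is.null(b)) stop("chromosome not in LiftMap: ", chrom)
  pseudo_len <- if (nrow(b)) max(b$pseudo_end) else 0L
  if (start < 0L || end > pseudo_len || start > end)
    stop("interval out of pseudogenome bounds: ", chrom, ":", start, "-", end)
  ov <- which(b$pseudo_end > start & b$pseudo_start < end)
  touches_ins <- any(b$kind[ov] == "INSERTED")
  m <- ov[b$kind[ov] == "MATCH"]
  if (length(m) == 0L) {
    # wholly inserted (or empty query): anchor of the covering block
    blk <- if (length(ov)) ov[1] else
      max(which(b$pseudo_start <= start))
    anchor <- if (b$kind[blk] == "INSERTED") b$ref_start[blk]
      else b$ref_start[blk] + (start - b$pseudo_start[blk])
    return(list(start = anchor, end = anchor,
                insertion_only = b$kind[blk] == "INSERTED",
                touches_insertion = touches_ins, spans_deletion = FALSE))
  }
  rs <- b$ref_start[m] + pmax(start - b$pseudo_start[m], 0L)
  re <- b$ref_end[m] - pmax(b$pseudo_end[m] - end, 0L)
  spans_del <- length(m) > 1L && any(rs[-1L] != re[-length(re)])
  list(start = min(rs), end = max(re),
       insertion_only = FALSE, touches_insertion = touches_ins,
       spans_deletion = spans_del)
}

#' Map reference positions into pseudogenome coordinates
#'
#' The inverse of the MATCH blocks of a [build_pseudogenome()] lift map:
#' each 0-based reference position is mapped to its 0-based pseudogenome
#' image, or `NA` if the position was deleted in the variant strain.
#'
#' @param liftmap a `LiftMap`.
#' @param chrom chromosome name.
#' @param pos integer vector of 0-based reference positions.
#' @return integer vector of 0-based pseudogenome positions (NA = deleted).
#' @export
ref_to_pseudo <- function(liftmap, chrom, pos) {
  b <- liftmap$blocks[[chrom]]
  if (is.null(b)) stop("chromosome not in LiftMap: ", chrom)
  m <- b[b$kind == "MATCH", , drop = FALSE]
  idx <- findInterval(pos, m$ref_start)
  out <- rep(NA_integer_, length(pos))
  ok <- idx >= 1L & pos < m$ref_end[pmax(idx, 1L)]
  out[ok] <- m$pseudo_start[idx[ok]] + (pos[ok] - m$ref_start[idx[ok]])
  out
}

#' Assemble a diploid hybrid genome
#'
#' Emits one sequence set with two records per chromosome, named
#' `<chrom>_<strain_a>` then `<chrom>_<strain_b>`, where strain A is the
#' reference strain and strain B the variant strain (pseudogenome).
#' Competitive mapping to this genome is what makes reads sort themselves
#' onto their haplotype of origin.
#'
#' @param ref reference `DNAStringSet` (strain A haplotype).
#' @param pseudo pseudogenome `DNAStringSet` (strain B haplotype).
#' @param strain_a,strain_b strain names used as record suffixes.
#' @return a `DNAStringSet` with `2 * nchrom` records.
#' @export
build_diploid_genome <- function(ref, pseudo, strain_a, strain_b) {
  if (strain_a == strain_b) stop("strain names must differ")
  if (!setequal(names(ref), names(pseudo)))
    stop("chromosome sets differ between reference and pseudogenome")
  if (length(ref) == 0L) stop("empty chromosome set")
  recs <- list()
  for (chrom in names(ref)) {
    recs[[paste0(chrom, "_", strain_a)]] <- ref[[chrom]]
    recs[[paste0(chrom, "_", strain_b)]] <- pseudo[[chrom]]
  }
  Biostrings::DNAStringSet(recs)
}

#' Split a diploid contig name into chromosome and strain
#' @param rname character vector of diploid contig names.
#' @param strains character vector of known strain suffixes.
#' @return data.frame with columns `chrom` and `strain`.
#' @export
split_diploid_name <- function(rname, strains) {
  pat <- paste0("_(", paste(strains, collapse = "|"), ")$")
  m <- regexpr(pat, rname)
  if (any(m < 0L))
    stop("contig name without a recognized strain suffix: ",
         paste(unique(rname[m < 0L]), collapse = ", "))
  data.frame(chrom = substr(rname, 1L, m - 1L),
             strain = substring(regmatches(rname, m), 2L),
             stringsAsFactors = FALSE)
}

#' Write / read a LiftMap as a tab-separated block file
#'
#' Chain-like plain-text serialization: header line
#' `chrom pseudo_start pseudo_end ref_start ref_end kind`, one row per
#' block, 0-based half-open coordinates (INSERTED rows carry the anchor in
#' `ref_start` = `ref_end`).
#'
#' @param liftmap a `LiftMap`.
#' @param path output file path.
#' @export
write_liftmap <- function(liftmap, path) {
  rows <- do.call(rbind, lapply(names(liftmap$blocks), function(chrom) {
    b <- liftmap$blocks[[chrom]]
    if (nrow(b) == 0L) return(NULL)
    cbind(data.frame(chrom = chrom, stringsAsFactors = FALSE), b)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_liftmap
#' @export
read_liftmap <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  blocks <- split(df[, setdiff(names(df), "chrom")], df$chrom)
  blocks <- lapply(blocks, function(b) { rownames(b) <- NULL; b })
  structure(list(blocks = blocks), class = "LiftMap")
}
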