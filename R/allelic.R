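#' Cross orientation of an F1 hybrid
#'
#' Records which inbred strain was the mother and which the father. The
#' strain names must match the suffixes used in the diploid genome, so that
#' the haplotype a read maps to can be translated into a parental origin.
#'
#' @param maternal_strain,paternal_strain distinct strain names.
#' @return a `CrossOrientation` object.
#' @export
cross_orientation <- function(maternal_strain, paternal_strain) {
  if (maternal_strain == paternal_strain)
    stop("maternal and paternal strains must differ")
  structure(list(maternal_strain = maternal_strain,
                 paternal_strain = paternal_strain),
            class = "CrossOrientation")
}

#' Swap mother and father of a cross
#' @param cross a `CrossOrientation`.
#' @return the reciprocal `CrossOrientation`.
#' @export
swap_cross <- function(cross) {
  cross_orientation(cross$paternal_strain, cross$maternal_strain)
}

#' Alignment filter settings for allelic classification
#'
#' Defaults mirror standard hybrid-pipeline filtering: MAPQ >= 20 and
#' proper pairs for RNA/ChIP-style paired data (`samtools view -f 2 -q 20`);
#' 4C interacting mates use MAPQ >= 10 and no pairing requirement. Low MAPQ
#' is the mechanism by which reads mapping equally well to both haplotypes
#' of the diploid genome end up unassigned: the aligner-reported MAPQ is
#' trusted, never recomputed.
#'
#' @param mapq_min minimum mapping quality (default 20).
#' @param require_proper_pair drop records without the proper-pair SAM flag.
#' @param drop_duplicates drop records carrying the SAM duplicate flag.
#' @return a `FilterConfig` object.
#' @export
filter_config <- function(mapq_min = 20L, require_proper_pair = TRUE,
                          drop_duplicates = FALSE) {
  stopifnot(mapq_min >= 0L)
  structure(list(mapq_min = as.integer(mapq_min),
                 require_proper_pair = isTRUE(require_proper_pair),
                 drop_duplicates = isTRUE(drop_duplicates)),
            class = "FilterConfig")
}

#' Classify diploid-genome alignments into maternal / paternal reads
#'
#' Splits the mapped contig name of each alignment into chromosome and
#' haplotype (strain suffix), applies the MAPQ / proper-pair / duplicate
#' filters, and derives the parental origin of every passing read from its
#' haplotype through the cross orientation. Records failing a filter are
#' returned separately with a reason, never silently discarded.
#'
#' @param aln alignment data.frame (see [read_alignments()]) mapped to a
#'   diploid genome whose contigs are suffixed `_<strain>`.
#' @param cross a [cross_orientation()].
#' @param cfg a [filter_config()].
#' @return list with `passed` (classified table: adds `chrom`, `haplotype`,
#'   `parent`, `hap_start`, `hap_end`) and `rejected` (input rows plus
#'   `filtered_reason`).
#' @export
classify_alignments <- function(aln, cross, cfg = filter_config()) {
  strains <- c(cross$maternal_strain, cross$paternal_strain)
  ns <- split_diploid_name(aln$rname, strains)
  reason <- rep(NA_character_, nrow(aln))
  if (cfg$drop_duplicates) reason[sam_is_dup(aln$flag)] <- "duplicate"
  if (cfg$require_proper_pair)
    reason[is.na(reason) & !sam_is_proper_pair(aln$flag)] <- "not_proper_pair"
  reason[is.na(reason) & aln$mapq < cfg$mapq_min] <- "low_mapq"
  ok <- is.na(reason)
  passed <- aln[ok, , drop = FALSE]
  passed$chrom <- ns$chrom[ok]
  passed$haplotype <- ns$strain[ok]
  passed$parent <- ifelse(passed$haplotype == cross$maternal_strain,
                          "maternal", "paternal")
  passed$hap_start <- passed$start
  passed$hap_end <- passed$end
  rejected <- aln[!ok, , drop = FALSE]
  rejected$filtered_reason <- reason[!ok]
  rownames(passed) <- rownames(rejected) <- NULL
  list(passed = passed, rejected = rejected)
}

#' Project classified alignments onto reference coordinates
#'
#' Replaces each alignment's interval by its lift-map image on the
#' reference, so maternal and paternal reads can be compared on one
#' coordinate system. Reference-strain alignments are untouched (identity
#' lift); variant-strain alignments go through [lift_interval()], and the
#' insertion/deletion flags are carried along as columns.
#'
#' @param aln `passed` table from [classify_alignments()].
#' @param liftmaps named list of `LiftMap`s, one per strain (a strain may
#'   map to `NULL` for identity).
#' @return the table with `start`/`end` in reference coordinates plus
#'   logical columns `insertion_only` and `spans_deletion`.
#' @export
project_to_reference <- function(aln, liftmaps) {
  n <- nrow(aln)
  aln$insertion_only <- rep(FALSE, n)
  aln$spans_deletion <- rep(FALSE, n)
  if (n == 0L) return(aln)
  for (strain in unique(aln$haplotype)) {
    lm <- liftmaps[[strain]]
    if (is.null(lm)) next
    idx <- which(aln$haplotype == strain)
    for (i in idx) {
      li <- lift_interval(lm, aln$chrom[i], aln$hap_start[i], aln$hap_end[i])
      aln$start[i] <- li$start
      aln$end[i] <- li$end
      aln$insertion_only[i] <- li$insertion_only
      aln$spans_deletion[i] <- li$spans_deletion
    }
  }
  aln
}

#' Per-SNP allelic pileup counts
#'
#' For every SNP in `snps`, counts the classified reads covering it whose
#' base matches the maternal-strain allele, the paternal-strain allele, or
#' neither (`other`, which also absorbs bases below `min_base_quality`).
#' The maternal fraction is `m / (m + p)`, reported as `NA` when no
#' informative read covers the SNP. Reads are interrogated in their own
#' haplotype's coordinates, so strain indels between the read and the SNP
#' are handled exactly via the lift map.
#'
#' @param aln classified alignment table (needs `haplotype`, `hap_start`,
#'   `seq`, optionally `qual`).
#' @param snps a `VariantSet` (only SNP records are used).
#' @param cross a [cross_orientation()].
#' @param strain_ref name of the reference strain (carries the `ref`
#'   allele); the other strain carries `alt`.
#' @param liftmaps named list of per-strain `LiftMap`s (identity may be
#'   `NULL`).
#' @param min_base_quality minimum Phred base quality; lower bases count as
#'   `other`.
#' @return data.frame with one row per SNP: `chrom`, `pos`,
#'   `maternal_count`, `paternal_count`, `other_count`,
#'   `maternal_fraction`.
#' @export
pileup_allelic_counts <- function(aln, snps, cross, strain_ref, liftmaps,
                                  min_base_quality = 0L) {
  snps <- snps[snps$kind == "SNP", , drop = FALSE]
  n <- nrow(snps)
  m_cnt <- p_cnt <- o_cnt <- integer(n)
  strains <- unique(aln$haplotype)
  for (s in seq_len(n)) {
    chrom <- snps$chrom[s]
    pos0 <- snps$pos[s] - 1L
    # allele carried by each strain at this SNP
    allele_of <- function(strain)
      if (strain == strain_ref) snps$ref[s] else snps$alt[s]
    mat_allele <- allele_of(cross$maternal_strain)
    pat_allele <- allele_of(cross$paternal_strain)
    for (strain in strains) {
      rows <- which(aln$haplotype == strain & aln$chrom == chrom)
      if (length(rows) == 0L) next
      lm <- liftmaps[[strain]]
      hap_pos <- if (is.null(lm)) pos0 else ref_to_pseudo(lm, chrom, pos0)
      if (is.na(hap_pos)) next  # SNP position deleted on this haplotype
      off <- hap_pos - aln$hap_start[rows]
      cov <- rows[off >= 0L & off < (aln$hap_end[rows] - aln$hap_start[rows])]
      if (length(cov) == 0L) next
      off <- hap_pos - aln$hap_start[cov]
      base <- substr(aln$seq[cov], off + 1L, off + 1L)
      if (min_base_quality > 0L && !is.null(aln$qual)) {
        q <- utf8ToInt_vec(aln$qual, off + 1L) - 33L
        base[q < min_base_quality] <- "?"
      }
      m_cnt[s] <- m_cnt[s] + sum(base == mat_allele)
      p_cnt[s] <- p_cnt[s] + sum(base == pat_allele)
      o_cnt[s] <- o_cnt[s] + sum(base != mat_allele & base != pat_allele)
    }
  }
  tot <- m_cnt + p_cnt
  data.frame(chrom = snps$chrom, pos = snps$pos,
             maternal_count = m_cnt, paternal_count = p_cnt,
             other_count = o_cnt,
             maternal_fraction = ifelse(tot > 0L, m_cnt / tot, NA_real_),
             stringsAsFactors = FALSE)
}

# Phred character at position k of each quality string.
utf8ToInt_vec <- function(qual, k) {
  vapply(substr(qual, k, k), function(ch)
    if (nchar(ch)) utf8ToInt(ch) else 0L, 0L)
}
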