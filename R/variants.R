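#' Construct a VariantSet from primitive records
#'
#' A `VariantSet` is a data.frame of primitive strain differences anchored on
#' the reference: one row per SNP, insertion or deletion, with columns
#' `chrom`, `pos` (1-based reference position of the VCF anchor base),
#' `ref` and `alt` allele strings, and `kind` (`"SNP"`, `"INS"` or `"DEL"`).
#' Records are sorted by `(chrom, pos)` and their reference footprints do not
#' overlap. All records are treated as fixed homozygous strain differences
#' (the F1 inbred-cross assumption); genotype fields are ignored.
#'
#' Non-primitive rows (MNPs, complex substitutions) and rows whose footprint
#' overlaps an earlier accepted record are dropped, not repaired: dropped
#' counts are kept in the `"report"` attribute so the load is auditable.
#'
#' @param df data.frame with columns chrom, pos, ref, alt (kind is derived).
#' @param report optional named list of drop counts to attach.
#' @return a `VariantSet` (data.frame subclass).
#' @export
variant_set <- function(df, report = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)))
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$kind <- variant_kind(df$ref, df$alt)
  if (anyNA(df$kind)) {
    stop("non-primitive variant record(s): ",
         paste(head(which(is.na(df$kind))), collapse = ", "))
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  keep <- resolve_overlaps(df)
  dropped_overlap <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  rep0 <- list(n_loaded = nrow(df), n_dropped_overlap = dropped_overlap,
               n_dropped_nonprimitive = 0L)
  if (!is.null(report)) rep0[names(report)] <- report
  rep0$n_dropped_overlap <- rep0$n_dropped_overlap %||% 0L
  attr(df, "report") <- rep0
  class(df) <- c("VariantSet", "data.frame")
  df
}

# SNP: both alleles length 1. INS: alt longer, ref a prefix of alt.
# DEL: ref longer, alt a prefix of ref. Everything else is non-primitive (NA).
variant_kind <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  kind <- rep(NA_character_, length(ref))
  kind[nr == 1L & na == 1L] <- "SNP"
  ins <- na > nr & substr(alt, 1L, nr) == ref & nr == 1L
  del <- nr > na & substr(ref, 1L, na) == alt & na == 1L
  kind[ins] <- "INS"
  kind[del] <- "DEL"
  kind
}

# Reference footprint of a record, 1-based inclusive [pos, pos+len(ref)-1].
variant_footprint_end <- function(pos, ref) pos + nchar(ref) - 1L

# First-wins overlap policy: scan sorted records per chromosome, drop any
# record whose footprint intersects an already-accepted record's footprint.
resolve_overlaps <- function(df) {
  keep <- rep(TRUE, nrow(df))
  if (nrow(df) < 2L) return(keep)
  last_end <- -Inf; last_chrom <- ""
  fe <- variant_footprint_end(df$pos, df$ref)
  for (i in seq_len(nrow(df))) {
    if (df$chrom[i] != last_chrom) { last_chrom <- df$chrom[i]; last_end <- -Inf }
    if (df$pos[i] <= last_end) { keep[i] <- FALSE; next }
    last_end <- fe[i]
  }
  keep
}

#' Load strain variants from a VCF file
#'
#' Reads a VCF 4.x file of strain-vs-reference differences, splits
#' multi-allelic rows, keeps only primitive SNP/INS/DEL records, applies the
#' first-wins overlap policy and returns a sorted [variant_set()]. The drop
#' counts (non-primitive, overlapping, symbolic/missing alleles) are stored
#' in the `"report"` attribute, retrievable with [load_report()].
#'
#' @param vcf_path path to a VCF file (plain or bgzipped).
#' @param reference optional `DNAStringSet`; when supplied, every record's
#'   CHROM must exist in it and `ref` must match the reference sequence at
#'   `pos`, otherwise a hard error is raised.
#' @return a `VariantSet`.
#' @export
load_variants <- function(vcf_path, reference = NULL) {
  if (!file.exists(vcf_path)) stop("no such file: ", vcf_path)
  validate_vcf_lines(vcf_path)
  v <- suppressWarnings(vcfR::read.vcfR(vcf_path, verbose = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(variant_set(data.frame(chrom = character(), pos = integer(),
                                  ref = character(), alt = character())))
  }
  # split multi-allelic ALT fields into one candidate record per allele
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  nalt <- lengths(alts)
  cand <- data.frame(
    chrom = rep(fix$CHROM, nalt),
    pos = rep(as.integer(fix$POS), nalt),
    ref = rep(toupper(fix$REF), nalt),
    alt = toupper(unlist(alts)),
    stringsAsFactors = FALSE
  )
  bad_allele <- !grepl("^[ACGT]+$", cand$ref) | !grepl("^[ACGT]+$", cand$alt)
  n_bad <- sum(bad_allele)
  cand <- cand[!bad_allele, , drop = FALSE]
  kind <- variant_kind(cand$ref, cand$alt)
  n_nonprim <- sum(is.na(kind))
  cand <- cand[!is.na(kind), , drop = FALSE]
  if (!is.null(reference)) {
    missing_chrom <- setdiff(unique(cand$chrom), names(reference))
    if (length(missing_chrom) > 0L)
      stop("VCF CHROM absent from reference: ",
           paste(missing_chrom, collapse = ", "))
    check_ref_alleles(reference, cand)
  }
  vs <- variant_set(cand)
  rep0 <- attr(vs, "report")
  rep0$n_dropped_nonprimitive <- n_nonprim
  rep0$n_dropped_bad_allele <- n_bad
  attr(vs, "report") <- rep0
  vs
}

# Minimal structural scan so a malformed body line fails with its number;
# full parsing is delegated to vcfR.
validate_vcf_lines <- function(vcf_path) {
  con <- if (grepl("\\.gz$", vcf_path)) gzfile(vcf_path) else file(vcf_path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 8L)
      stop("unparseable VCF line ", i, ": expected >= 8 tab-separated fields")
    if (is.na(suppressWarnings(as.integer(fields[2]))))
      stop("unparseable VCF line ", i, ": POS is not an integer")
  }
  invisible(TRUE)
}

check_ref_alleles <- function(reference, df) {
  if (nrow(df) == 0L) return(invisible(TRUE))
  for (chrom in unique(df$chrom)) {
    sel <- df$chrom == chrom
    seq <- reference[[chrom]]
    ends <- variant_footprint_end(df$pos[sel], df$ref[sel])
    if (any(ends > length(seq)))
      stop("variant footprint beyond end of ", chrom)
    obs <- as.character(Biostrings::extractAt(
      seq, IRanges::IRanges(df$pos[sel], ends)))
    bad <- which(obs != df$ref[sel])
    if (length(bad) > 0L) {
      b <- which(sel)[bad[1]]
      stop("ref allele mismatch at ", chrom, ":", df$pos[b],
           " (VCF says ", df$ref[b], ", reference has ", obs[bad[1]], ")")
    }
  }
  invisible(TRUE)
}

#' Retrieve the load/processing report attached to an object
#'
#' @param x an object with a `"report"` attribute (e.g. a `VariantSet`).
#' @return a named list of counts.
#' @export
load_report <- function(x) attr(x, "report")

#' @export
print.VariantSet <- function(x, ...) {
  rep0 <- attr(x, "report")
  cat("VariantSet with", nrow(x), "records (",
      sum(x$kind == "SNP"), "SNP,", sum(x$kind == "INS"), "INS,",
      sum(x$kind == "DEL"), "DEL )\n")
  if (!is.null(rep0))
    cat("  dropped:", rep0$n_dropped_overlap %||% 0L, "overlapping,",
        rep0$n_dropped_nonprimitive %||% 0L, "non-primitive\n")
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}
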