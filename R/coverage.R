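#' Coverage track settings
#'
#' Bin size and normalization defaults follow common practice for each
#' assay: ChIP-style tracks use 20-bp bins with reads extended to 200 bp
#' from their 5' end; Cut&Run tracks use 25-bp bins. RPKM per bin is
#' `count * 1e9 / (bin_size * total_mapped)`.
#'
#' @param bin_size bin width in bp (>= 1).
#' @param extend_reads extension length in bp from the 5' end, or `NULL`
#'   for no extension (single-end-style records only).
#' @param normalization one of `"RPKM"`, `"scale_factor"`, `"raw"`.
#' @param strand_mode one of `"none"`, `"forward"`, `"reverse"` (stranded
#'   RNA coverage under the fr-firststrand convention).
#' @param ignore_duplicates drop SAM-flagged duplicates before binning.
#' @param scale_factor multiplicative factor applied to bin values when
#'   `normalization = "scale_factor"` (e.g. from [spike_in_factor()]).
#' @return a `CoverageConfig` object.
#' @export
coverage_config <- function(bin_size = 20L, extend_reads = NULL,
                            normalization = c("RPKM", "scale_factor", "raw"),
                            strand_mode = c("none", "forward", "reverse"),
                            ignore_duplicates = FALSE, scale_factor = 1) {
  stopifnot(bin_size >= 1L)
  structure(list(bin_size = as.integer(bin_size),
                 extend_reads = if (is.null(extend_reads)) NULL
                                else as.integer(extend_reads),
                 normalization = match.arg(normalization),
                 strand_mode = match.arg(strand_mode),
                 ignore_duplicates = isTRUE(ignore_duplicates),
                 scale_factor = scale_factor),
            class = "CoverageConfig")
}

#' Binned, normalized coverage track
#'
#' Tiles each chromosome with fixed-width bins and counts, per bin, the
#' alignments overlapping it: a read overlapping k bins contributes one
#' count to each of the k bins (not fractionally). With
#' `normalization = "RPKM"` each bin count is scaled by
#' `1e9 / (bin_size * total_mapped)`; the final, truncated bin still uses
#' the nominal bin size in the denominator. Optional 5'-end read extension
#' is applied before binning, clipped at chromosome ends.
#'
#' @param aln alignment table in reference coordinates (`chrom` or `rname`,
#'   `start`, `end` 0-based half-open, `strand`, `flag`).
#' @param seqlengths named integer vector of chromosome lengths.
#' @param cfg a [coverage_config()].
#' @param total_mapped total mapped reads for the RPKM denominator
#'   (defaults to `nrow(aln)` after duplicate removal).
#' @return a `Track`: list with `values` (named list of per-bin numeric
#'   vectors), `bin_size`, and metadata `total_mapped`, `scale_factor`.
#' @export
binned_coverage <- function(aln, seqlengths, cfg = coverage_config(),
                            total_mapped = NULL) {
  chrom <- aln$chrom %||% aln$rname
  if (cfg$ignore_duplicates) {
    keep <- !sam_is_dup(aln$flag %||% integer(nrow(aln)))
    aln <- aln[keep, , drop = FALSE]
    chrom <- chrom[keep]
  }
  if (is.null(total_mapped)) total_mapped <- nrow(aln)
  if (cfg$normalization == "RPKM" && total_mapped <= 0L)
    stop("RPKM normalization requires total_mapped > 0")
  start <- aln$start; end <- aln$end
  if (!is.null(cfg$extend_reads)) {
    fwd <- aln$strand != "-"
    end[fwd] <- pmin(start[fwd] + cfg$extend_reads,
                     seqlengths[chrom[fwd]])
    start[!fwd] <- pmax(end[!fwd] - cfg$extend_reads, 0L)
  }
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start + 1L, end = pmax(end, start + 1L)))
  values <- lapply(names(seqlengths), function(chr) {
    len <- seqlengths[[chr]]
    nb <- ceiling(len / cfg$bin_size)
    bs <- (seq_len(nb) - 1L) * cfg$bin_size
    bins <- GenomicRanges::GRanges(
      chr, IRanges::IRanges(start = bs + 1L, end = pmin(bs + cfg$bin_size, len)))
    cnt <- GenomicRanges::countOverlaps(bins, gr)
    switch(cfg$normalization,
           RPKM = cnt * 1e9 / (cfg$bin_size * total_mapped),
           scale_factor = cnt * cfg$scale_factor,
           raw = as.numeric(cnt))
  })
  names(values) <- names(seqlengths)
  structure(list(values = values, bin_size = cfg$bin_size,
                 seqlengths = seqlengths,
                 total_mapped = total_mapped,
                 scale_factor = cfg$scale_factor),
            class = "Track")
}

#' Strand-split RNA coverage (fr-firststrand)
#'
#' Stranded coverage of paired RNA-seq fragments under the fr-firststrand
#' library convention: a fragment belongs to the forward (plus-strand
#' transcribed) track when its read 2 maps to `+`, equivalently read 1 maps
#' to `-`. Each fragment is counted once, through its read-1 record.
#'
#' @inheritParams binned_coverage
#' @param cfg a [coverage_config()] with `strand_mode` `"forward"` or
#'   `"reverse"`.
#' @return a `Track` for the requested strand.
#' @export
strand_split_coverage <- function(aln, seqlengths, cfg, total_mapped = NULL) {
  if (cfg$strand_mode == "none")
    stop("strand_split_coverage needs strand_mode 'forward' or 'reverse'")
  flag <- aln$flag
  if (is.null(flag) || !any(sam_is_paired(flag)))
    stop("strand-split coverage requires paired records")
  r1 <- sam_is_read1(flag)
  want_rev1 <- cfg$strand_mode == "forward"  # read1 on '-' => forward fragment
  keep <- r1 & (sam_is_reverse(flag) == want_rev1)
  if (is.null(total_mapped)) total_mapped <- sum(r1)
  sub_cfg <- cfg
  sub_cfg$strand_mode <- "none"
  binned_coverage(aln[keep, , drop = FALSE], seqlengths, sub_cfg,
                  total_mapped = total_mapped)
}

#' Spike-in scale factor
#'
#' Exogenous-DNA (e.g. E. coli) normalization for Cut&Run: the factor is
#' `reference_constant / sample_spikein_reads`, applied multiplicatively to
#' bin values, so samples with deeper spike-in recovery are scaled down.
#' The reference constant is a free choice shared across the samples being
#' compared; only ratios between samples are meaningful.
#'
#' @param sample_spikein_reads spike-in read count for this sample (> 0).
#' @param reference_constant shared constant (default 1e4).
#' @return a scalar scale factor.
#' @export
spike_in_factor <- function(sample_spikein_reads, reference_constant = 1e4) {
  if (sample_spikein_reads <= 0L) stop("spike-in read count must be > 0")
  reference_constant / sample_spikein_reads
}

#' Write a Track as a bedGraph file
#'
#' 4-column, 0-based half-open bedGraph; runs of adjacent equal-value bins
#' are merged on write.
#'
#' @param track a `Track` from [binned_coverage()].
#' @param path output path.
#' @param digits number of significant digits for values.
#' @export
write_bedgraph <- function(track, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$values)) {
    v <- track$values[[chr]]
    if (length(v) == 0L) next
    r <- rle(signif(v, digits))
    ends0 <- cumsum(r$lengths) * track$bin_size
    starts0 <- c(0L, utils::head(ends0, -1L))
    ends0 <- pmin(ends0, track$seqlengths[[chr]])
    writeLines(paste(chr, starts0, ends0, format(r$values, trim = TRUE,
                                                 scientific = FALSE)), con)
  }
  invisible(path)
}
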