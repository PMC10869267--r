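#' Read alignments from SAM/BAM into a flat table
#'
#' Loads an alignment file through Rsamtools and returns the plain
#' data.frame representation used throughout the package: one row per
#' alignment with columns `qname`, `flag`, `rname`, `start`, `end`
#' (0-based half-open on the mapped contig), `strand`, `mapq`, `cigar`,
#' `seq`, `qual`. SAM input is converted to BAM in a temporary directory
#' first. Unmapped records are dropped.
#'
#' @param path path to a SAM or BAM file.
#' @return data.frame of alignment records.
#' @export
read_alignments <- function(path) {
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar)
  data.frame(
    qname = b$qname,
    flag = b$flag,
    rname = as.character(b$rname),
    start = b$pos - 1L,
    end = b$pos - 1L + rw,
    strand = ifelse(sam_is_reverse(b$flag), "-", "+"),
    mapq = b$mapq,
    cigar = b$cigar,
    seq = as.character(b$seq),
    qual = as.character(b$qual),
    stringsAsFactors = FALSE
  )
}

#' Write an alignment table as a SAM file
#'
#' Serializes the package's flat alignment table (see [read_alignments()])
#' to a headered SAM file. Used by the simulators so that pipelines can be
#' exercised from files exactly as they would be on real data.
#'
#' @param aln alignment data.frame (`start` 0-based half-open).
#' @param seqlengths named integer vector of contig lengths for the header.
#' @param path output path.
#' @export
write_sam <- function(aln, seqlengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(seqlengths), "\tLN:",
                  as.integer(seqlengths)))
  if (nrow(aln) > 0L) {
    cig <- aln$cigar %||% paste0(nchar(aln$seq), "M")
    qual <- aln$qual %||% strrep("I", nchar(aln$seq))
    body <- paste(aln$qname, aln$flag, aln$rname, aln$start + 1L,
                  aln$mapq, cig,
                  aln$mrnm %||% "*", (aln$mpos %||% -1L) + 1L,
                  aln$isize %||% 0L,
                  aln$seq, qual, sep = "\t")
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
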