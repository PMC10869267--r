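# Shared fixtures, built lazily and cached for the test run.

toy_ref <- function() Biostrings::DNAStringSet(c(chrT = "AACGTT"))

toy_snp <- function() variant_set(
  data.frame(chrom = "chrT", pos = 3L, ref = "C", alt = "G"))

toy_ins <- function() variant_set(
  data.frame(chrom = "chrT", pos = 2L, ref = "A", alt = "ATT"))

toy_del <- function() variant_set(
  data.frame(chrom = "chrT", pos = 2L, ref = "ACG", alt = "A"))

bj_cross <- function() cross_orientation("B6", "JF1")

# Toy paired SAM-style alignment record on a diploid contig.
toy_record <- function(rname = "chrT_JF1", mapq = 30L, flag = 99L,
                       start = 0L, end = 4L, seq = "AATT") {
  data.frame(qname = "r1", flag = flag, rname = rname, start = start,
             end = end, strand = if (bitwAnd(flag, 0x10L) > 0L) "-" else "+",
             mapq = mapq, cigar = paste0(end - start, "M"), seq = seq,
             qual = strrep("I", end - start), stringsAsFactors = FALSE)
}

# Cache for expensive simulated objects shared by several test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

# A 420 kb contig with strain variants and a viewpoint around a SNP close
# to the central bait: the base configuration of the 4C simulations.
fourc_base <- function() cached("fourc_base", function() {
  ref <- simulate_reference(c(chr4C = 420000L), seed = 5L)
  vs <- simulate_strain_variants(ref, seed = 5L)
  bait <- 210000L
  sp <- vs[vs$kind == "SNP" & abs(vs$pos - bait) < 2000L, ][1L, ]
  vp <- viewpoint_spec("chr4C", sp$pos - 30L, sp$pos + 30L, sp$pos,
                       sp$ref, sp$alt)
  fragmap <- digest_genome(ref)
  win <- window_fragends(fragmap, "chr4C", bait, k = 8L)
  list(ref = ref, variants = vs, bait = bait, vp = vp,
       fragmap = fragmap, windows = win)
})

# Anchor one window ~100 kb downstream of the bait (promoter-enhancer
# loop span scale): returns the anchor window row index and position.
loop_anchor <- function(base) {
  wi <- which.min(abs(base$windows$start - (base$bait + 100000L)))
  list(index = wi, pos = base$windows$start[wi],
       start = base$windows$start[wi], end = base$windows$end[wi])
}
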