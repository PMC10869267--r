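make_reads <- function(n, chrom = "chrS", start = 100L, width = 50L,
                       strand = "+", flag = NULL) {
  if (is.null(flag)) flag <- rep(0L, n)
  data.frame(qname = paste0("r", seq_len(n)), flag = flag, chrom = chrom,
             start = rep(start, n), end = rep(start + width, n),
             strand = strand, stringsAsFactors = FALSE)
}

test_that("RPKM follows its closed form and raw counts are untouched", {
  sl <- c(chrS = 1000L)
  reads <- make_reads(10L, start = 210L, width = 60L)  # inside bin [200,400)
  cfg <- coverage_config(bin_size = 200L)
  tr <- binned_coverage(reads, sl, cfg, total_mapped = 1e6)
  expect_equal(tr$values$chrS[2], 50)                  # 10 * 1e9/(200*1e6)
  expect_equal(sum(tr$values$chrS > 0), 1L)
  raw <- binned_coverage(reads, sl, coverage_config(bin_size = 200L,
                                                    normalization = "raw"))
  expect_equal(raw$values$chrS[2], 10)
  # duplicating every read doubles raw but leaves RPKM unchanged
  tr2 <- binned_coverage(rbind(reads, reads), sl, cfg, total_mapped = 2e6)
  expect_equal(tr2$values$chrS, tr$values$chrS)
  expect_error(binned_coverage(reads, sl, cfg, total_mapped = 0),
               "total_mapped")
})

test_that("multi-bin reads count once per overlapped bin; extension works", {
  sl <- c(chrS = 1000L)
  # one read spanning bins 1 and 2
  r <- make_reads(1L, start = 150L, width = 100L)
  raw <- binned_coverage(r, sl, coverage_config(bin_size = 200L,
                                                normalization = "raw"))
  expect_equal(raw$values$chrS, c(1, 1, 0, 0, 0))
  # 5'-end extension to 200 bp pushes a + read into the next bin
  r2 <- make_reads(1L, start = 150L, width = 40L)
  ext <- binned_coverage(r2, sl, coverage_config(bin_size = 200L,
                                                 extend_reads = 200L,
                                                 normalization = "raw"))
  expect_equal(ext$values$chrS, c(1, 1, 0, 0, 0))
  # a - read extends leftwards from its 3' end
  r3 <- make_reads(1L, start = 210L, width = 40L, strand = "-")
  ext2 <- binned_coverage(r3, sl, coverage_config(bin_size = 200L,
                                                  extend_reads = 200L,
                                                  normalization = "raw"))
  expect_equal(ext2$values$chrS, c(1, 1, 0, 0, 0))
})

test_that("mass is conserved for single-bin reads", {
  set.seed(4)
  sl <- c(chrS = 10000L)
  starts <- sample.int(9900L, 500L) - 1L
  starts <- starts - (starts %% 20L)          # align into 20-bp bins
  reads <- data.frame(qname = paste0("r", 1:500), flag = 0L, chrom = "chrS",
                      start = starts, end = starts + 20L, strand = "+")
  raw <- binned_coverage(reads, sl, coverage_config(bin_size = 20L,
                                                    normalization = "raw"))
  expect_equal(sum(raw$values$chrS), 500)
})

test_that("fr-firststrand fragments land on the transcribed strand track", {
  sl <- c(chrS = 1000L)
  # + strand gene fragment: read1 on '-', read2 on '+'
  frag <- data.frame(qname = c("f1", "f1"), flag = c(83L, 163L),
                     chrom = "chrS", start = c(300L, 100L),
                     end = c(400L, 200L), strand = c("-", "+"))
  cfg_f <- coverage_config(bin_size = 200L, normalization = "raw",
                           strand_mode = "forward")
  cfg_r <- coverage_config(bin_size = 200L, normalization = "raw",
                           strand_mode = "reverse")
  fwd <- strand_split_coverage(frag, sl, cfg_f)
  rev <- strand_split_coverage(frag, sl, cfg_r)
  expect_equal(sum(fwd$values$chrS), 1)       # counted once, via read1
  expect_equal(sum(rev$values$chrS), 0)
  expect_error(strand_split_coverage(make_reads(2L), sl, cfg_f), "paired")
  # simulated + strand gene: all mass forward, none reverse
  ref <- simulate_reference(c(chrS = 20000L), seed = 3L)
  vs <- simulate_strain_variants(ref, seed = 3L)
  genes <- data.frame(name = "g1", chrom = "chrS", start = 2000L,
                      end = 18000L, strand = "+", maternal_fraction = 0.5,
                      n_fragments = 100L)
  sim <- simulate_allelic_reads(ref, vs, genes, bj_cross(), seed = 17L)
  aln <- sim$alignments
  aln$chrom <- split_diploid_name(aln$rname, c("B6", "JF1"))$chrom
  sl2 <- c(chrS = 21000L)
  f2 <- strand_split_coverage(aln, sl2, coverage_config(
    bin_size = 1000L, normalization = "raw", strand_mode = "forward"))
  r2 <- strand_split_coverage(aln, sl2, coverage_config(
    bin_size = 1000L, normalization = "raw", strand_mode = "reverse"))
  expect_gte(sum(f2$values$chrS), 100)
  expect_equal(sum(r2$values$chrS), 0)
})

test_that("allelic raw tracks add up to the total track bin-wise", {
  ref <- simulate_reference(c(chrS = 20000L), seed = 3L)
  vs <- simulate_strain_variants(ref, seed = 3L)
  genes <- data.frame(name = "g1", chrom = "chrS", start = 1000L,
                      end = 19000L, strand = "+", maternal_fraction = 0.6,
                      n_fragments = 400L)
  sim <- simulate_allelic_reads(ref, vs, genes, bj_cross(), seed = 19L)
  cl <- classify_alignments(sim$alignments, bj_cross(),
                            filter_config(mapq_min = 0L))
  aln <- project_to_reference(cl$passed, sim$liftmaps)
  sl <- c(chrS = 20000L)
  cfg <- coverage_config(bin_size = 500L, normalization = "raw")
  tot <- binned_coverage(aln, sl, cfg)
  parts <- lapply(c("maternal", "paternal"), function(p)
    binned_coverage(aln[aln$parent == p, , drop = FALSE], sl, cfg))
  # no unassigned class survives mapq_min = 0, so maternal + paternal = all
  expect_equal(parts[[1]]$values$chrS + parts[[2]]$values$chrS,
               tot$values$chrS)
})

test_that("spike-in scaling is a ratio and removes depth differences", {
  expect_equal(spike_in_factor(10000, 1e4), 1)
  expect_equal(spike_in_factor(20000, 1e4), 0.5)
  expect_error(spike_in_factor(0), "> 0")
  # equal true signal at 2x depth and 2x spike-in: scaled tracks equal
  sl <- c(chrS = 1000L)
  r1 <- make_reads(20L, start = 210L, width = 60L)
  r2 <- rbind(r1, r1)
  t1 <- binned_coverage(r1, sl, coverage_config(
    bin_size = 200L, normalization = "scale_factor",
    scale_factor = spike_in_factor(5000)))
  t2 <- binned_coverage(r2, sl, coverage_config(
    bin_size = 200L, normalization = "scale_factor",
    scale_factor = spike_in_factor(10000)))
  expect_equal(t1$values$chrS, t2$values$chrS, tolerance = 1e-12)
})

test_that("bedGraph output is 0-based half-open with merged runs", {
  sl <- c(chrS = 450L)
  reads <- make_reads(3L, start = 0L, width = 450L)
  tr <- binned_coverage(reads, sl, coverage_config(bin_size = 100L,
                                                   normalization = "raw"))
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  lines <- readLines(f)
  expect_equal(length(lines), 1L)  # constant value: one merged run
  expect_equal(strsplit(lines, " ")[[1]], c("chrS", "0", "450", "3"))
})
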