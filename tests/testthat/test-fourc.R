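test_that("in silico digestion cuts before every site occurrence", {
  g <- Biostrings::DNAStringSet(c(c1 = "AAGATCTTGATCCA"))
  fm <- digest_genome(g)
  expect_equal(fm$fragments$c1$start, c(0L, 2L, 8L))
  expect_equal(fm$fragments$c1$end, c(2L, 8L, 14L))
  expect_equal(fm$fragends$c1, c(0L, 2L, 8L, 14L))
  # no site: a single fragment spanning the contig
  g2 <- Biostrings::DNAStringSet(c(c1 = "AAAAAAAA"))
  expect_equal(nrow(digest_genome(g2)$fragments$c1), 1L)
  # string-search oracle on a random 10 kb contig
  ref <- simulate_reference(c(chrS = 10000L), seed = 8L)
  fm3 <- digest_genome(ref)
  hits <- gregexpr("GATC", as.character(ref[[1]]), fixed = TRUE)[[1]]
  n_occ <- if (hits[1] == -1L) 0L else length(hits)
  expect_equal(nrow(fm3$fragments$chrS), n_occ + 1L)
  expect_error(digest_genome(ref, "gatc"), "uppercase")
})

test_that("viewpoint demultiplexing assigns alleles from the SNP base", {
  vp <- viewpoint_spec("chrS", 100L, 160L, 131L, "A", "G")
  mk_pair <- function(base, mapq = 42L, start = 100L, qname = "p1") {
    s <- strrep("T", 60L)
    substr(s, 131L - start, 131L - start) <- base
    data.frame(qname = qname, vp_chrom = "chrS", vp_start = start,
               vp_end = start + 60L, vp_mapq = mapq, vp_seq = s,
               int_seq = strrep("C", 80L), stringsAsFactors = FALSE)
  }
  dm <- demultiplex_viewpoint_pairs(mk_pair("A"), vp)
  expect_equal(dm$allele, "maternal")
  dm2 <- demultiplex_viewpoint_pairs(mk_pair("G"), vp)
  expect_equal(dm2$allele, "paternal")
  # third allele / N: discarded and reported
  dm3 <- demultiplex_viewpoint_pairs(mk_pair("N"), vp)
  expect_equal(nrow(dm3), 0L)
  expect_equal(attr(dm3, "report")$n_allele_mismatch, 1L)
  # low-MAPQ and off-viewpoint pairs are discarded with their own reasons
  dm4 <- demultiplex_viewpoint_pairs(rbind(mk_pair("A", mapq = 3L),
                                           mk_pair("A", start = 5000L)), vp)
  expect_equal(attr(dm4, "report")$n_low_mapq, 1L)
  expect_equal(attr(dm4, "report")$n_off_viewpoint, 1L)
  # trimming the interacting mate
  dm5 <- demultiplex_viewpoint_pairs(mk_pair("A"), vp)
  expect_equal(nchar(dm5$int_seq_trimmed), 70L)
  # an uninformative viewpoint is rejected at construction
  expect_error(viewpoint_spec("chrS", 100L, 160L, 131L, "A", "A"),
               "uninformative")
})

test_that("demultiplexing recovers a programmed 60:40 allele mix", {
  base <- fourc_base()
  n <- 2000L
  sim <- simulate_4c_experiment(base$ref, "chr4C", base$bait, base$vp,
                                n_reads = n, replicates = 1L, seed = 77L)
  # keep a 60:40 maternal:paternal subsample
  keep <- c(which(sim$truth$allele == "maternal")[1:1200],
            which(sim$truth$allele == "paternal")[1:800])
  dm <- demultiplex_viewpoint_pairs(sim$pairs[keep, ], base$vp)
  frac <- mean(dm$allele == "maternal")
  se <- sqrt(0.6 * 0.4 / 2000)
  expect_lt(abs(frac - 0.6), 3 * se)
  # and every tag matches the simulation truth
  truth <- stats::setNames(sim$truth$allele, sim$truth$qname)
  expect_equal(sum(dm$allele != truth[dm$qname]), 0L)
})

test_that("fragend counting is exact against a brute-force oracle", {
  g <- Biostrings::DNAStringSet(c(c1 = "AAGATCTTGATCCA"))
  fm <- digest_genome(g)
  aln <- data.frame(qname = c("a", "b", "c"),
                    chrom = "c1", start = c(2L, 3L, 4L),
                    end = c(7L, 8L, 8L), strand = c("+", "+", "-"),
                    allele = "maternal", replicate = 1L)
  tab <- count_fragends(aln, fm)
  # +@2 hits the left fragend of [2,8); +@3 is off-grid; -ending@8 hits 8
  expect_equal(tab$fragend, c(2L, 8L))
  expect_equal(tab$count, c(1L, 1L))
  expect_equal(attr(tab, "n_dropped"), 1L)
  # randomized instance vs per-read boundary scan
  base <- fourc_base()
  sim <- simulate_4c_experiment(base$ref, "chr4C", base$bait, base$vp,
                                n_reads = 500L, replicates = 1L,
                                frac_offgrid = 0.2, seed = 31L)
  aln2 <- sim$interacting
  aln2$allele <- sim$truth$allele
  tab2 <- count_fragends(aln2, base$fragmap)
  fr <- base$fragmap$fragments$chr4C
  brute <- integer(nrow(aln2))
  for (i in seq_len(nrow(aln2))) {
    hit <- if (aln2$strand[i] == "+") aln2$start[i] %in% fr$start
           else aln2$end[i] %in% fr$end
    brute[i] <- if (hit) 1L else 0L
  }
  expect_equal(sum(tab2$count), sum(brute))
  expect_equal(attr(tab2, "n_dropped"), sum(brute == 0L))
  # per-fragend spot check against the same oracle
  fe_brute <- table(ifelse(aln2$strand == "+", aln2$start,
                           aln2$end)[brute == 1L])
  fe_pkg <- tapply(tab2$count, tab2$fragend, sum)
  expect_equal(sort(as.integer(fe_pkg)), sort(as.integer(fe_brute)))
})

test_that("rpm tracks sum to one million and smoothing behaves", {
  base <- fourc_base()
  sim <- simulate_4c_experiment(base$ref, "chr4C", base$bait, base$vp,
                                n_reads = 1000L, replicates = 2L, seed = 41L)
  aln <- sim$interacting
  aln$allele <- sim$truth$allele
  tab <- count_fragends(aln, base$fragmap)
  tr <- fragend_rpm_smooth(tab, base$fragmap, "chr4C", k = 8L)
  for (al in c("maternal", "paternal")) for (j in 1:2)
    expect_equal(sum(tr$rpm[[al]][, j]), 1e6)
  # closed forms on a constructed table
  tab2 <- data.frame(chrom = "c1", fragend = c(0L, 2L, 8L),
                     allele = "maternal", replicate = 1L,
                     count = c(0L, 3L, 6L))
  attr(tab2, "totals") <- data.frame(allele = "maternal", replicate = 1L,
                                     total = 1000L)
  g <- Biostrings::DNAStringSet(c(c1 = "AAGATCTTGATCCA"))
  fm <- digest_genome(g)
  tr2 <- fragend_rpm_smooth(tab2, fm, "c1", k = 3L)
  expect_equal(tr2$rpm$maternal[2:3, 1], c(3000, 6000))  # count*1e6/total
  # centered mean over [0, 3000, 6000] at the middle point
  expect_equal(unname(tr2$smoothed$maternal[2, 1]), 3000)
  # constant counts over the whole grid: smoothing is the identity
  tab3 <- data.frame(chrom = "c1", fragend = c(0L, 2L, 8L, 14L),
                     allele = "maternal", replicate = 1L, count = 5L)
  attr(tab3, "totals") <- data.frame(allele = "maternal", replicate = 1L,
                                     total = 20L)
  tr3 <- fragend_rpm_smooth(tab3, fm, "c1", k = 3L)
  expect_equal(tr3$smoothed$maternal[, 1], tr3$rpm$maternal[, 1])
})

test_that("ratio tracks are antisymmetric with pseudocount symmetry", {
  expect_equal(interaction_ratio_track(0, 0), 0)
  expect_equal(interaction_ratio_track(3, 1, pseudocount = 1), 1)
  set.seed(6)
  m <- rexp(50, 1 / 100); p <- rexp(50, 1 / 100)
  expect_equal(interaction_ratio_track(m, p),
               -interaction_ratio_track(p, m))
  expect_error(interaction_ratio_track(m, p[-1]), "grids")
})

test_that("domain calling flags an injected loop on the right allele only", {
  base <- fourc_base()
  an <- loop_anchor(base)
  anchors <- data.frame(pos = an$pos, maternal_mult = 5, paternal_mult = 1)
  sim <- simulate_4c_experiment(base$ref, "chr4C", base$bait, base$vp,
                                anchors = anchors, n_reads = 5000L,
                                replicates = 2L, seed = 303L)
  res <- fourc_run(sim$pairs, sim$interacting, base$vp, sim$fragmap,
                   "chr4C", base$bait)
  md <- res$domains$maternal$domains
  pd <- res$domains$paternal$domains
  expect_true(any(md$start <= an$end & md$end >= an$start))
  expect_false(nrow(pd) > 0 && any(pd$start <= an$end & pd$end >= an$start))
  # uniform zero counts: no domains
  tab0 <- res$fragends[0, , drop = FALSE]
  attr(tab0, "totals") <- data.frame(allele = character(),
                                     replicate = integer(),
                                     total = integer())
  d0 <- call_interaction_domains(tab0, base$fragmap, "chr4C", base$bait,
                                 allele = "maternal")
  expect_equal(nrow(d0$domains), 0L)
})

test_that("the paired differential test is calibrated and finds the loop", {
  base <- fourc_base()
  an <- loop_anchor(base)
  anchors <- data.frame(pos = an$pos, maternal_mult = 5, paternal_mult = 1)
  sim <- simulate_4c_experiment(base$ref, "chr4C", base$bait, base$vp,
                                anchors = anchors, n_reads = 5000L,
                                replicates = 2L, seed = 304L)
  res <- fourc_run(sim$pairs, sim$interacting, base$vp, sim$fragmap,
                   "chr4C", base$bait)
  d <- res$differential
  w <- which(d$start <= an$pos & d$end >= an$pos)
  expect_true(any(d$significant[w]))
  expect_true(all(d$log2_ratio[w] > 0))
  expect_true(all(d$padj >= d$p, na.rm = TRUE))
  # a perfectly balanced single-replicate window cannot be significant
  expect_equal(betabinom_test_twosided(30L, 60L, 0.5, 0), 1)
  # with rho = 0 the test reduces to the exact binomial test
  expect_equal(betabinom_test_twosided(20L, 60L, 0.5, 0),
               stats::binom.test(20L, 60L, 0.5)$p.value)
  # BH step-up arithmetic on the documented example
  expect_equal(stats::p.adjust(c(0.001, 0.02, 0.03, 0.5), method = "BH"),
               c(0.004, 0.04, 0.04, 0.5))
})

test_that("swapping the cross swaps track roles and ratio signs exactly", {
  base <- fourc_base()
  sim <- simulate_4c_experiment(base$ref, "chr4C", base$bait, base$vp,
                                n_reads = 1500L, replicates = 1L, seed = 55L)
  res <- fourc_run(sim$pairs, sim$interacting, base$vp, sim$fragmap,
                   "chr4C", base$bait)
  # the reciprocal cross: the strain bases at the viewpoint SNP trade places
  vp_sw <- viewpoint_spec(base$vp$chrom, base$vp$start, base$vp$end,
                          base$vp$snp_pos, base$vp$snp_paternal,
                          base$vp$snp_maternal)
  res_sw <- fourc_run(sim$pairs, sim$interacting, vp_sw, sim$fragmap,
                      "chr4C", base$bait)
  expect_equal(res_sw$ratio, -res$ratio)
  expect_equal(res_sw$tracks$mean$maternal, res$tracks$mean$paternal)
  expect_equal(res_sw$differential$log2_ratio, -res$differential$log2_ratio)
  expect_equal(res_sw$differential$p, res$differential$p)
})
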