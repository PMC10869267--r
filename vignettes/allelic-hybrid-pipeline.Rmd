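---
title: "Allele-specific analysis of F1 hybrid sequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific analysis of F1 hybrid sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

In an F1 hybrid between two inbred strains (for example C57BL/6 x JF1 in
mouse), every autosomal locus carries one maternal and one paternal allele
that differ at known strain polymorphisms. Reads that overlap such a
polymorphism can be assigned to their parental chromosome, which turns
ordinary RNA-seq, ChIP-seq, Cut&Run or 4C-seq into *allele-specific*
assays — the readout needed to study genomic imprinting, where the two
parental alleles of a domain behave differently by design.

`allelome` implements the computational side of this design as composable
R functions:

1. **genome products** — an N-masked reference, a variant-strain
   pseudogenome with an indel-aware lift map, and a diploid genome for
   competitive mapping;
2. **allelic classification** — haplotype-of-mapping on the diploid
   genome, projection back to reference coordinates, per-SNP allelic
   pileups;
3. **coverage tracks** — RPKM bins, fr-firststrand strand splitting,
   spike-in scaling;
4. **allelic 4C-seq** — viewpoint-allele demultiplexing, in silico DpnII
   digestion, exact fragment-end counting, smoothed rpm and log2 ratio
   tracks, near-bait domain calling, and a paired maternal-vs-paternal
   differential test;
5. **synthetic data** — seeded generators for every input, with ground
   truth, so each stage is testable end to end without external data.

# Genome products and the lift map

`build_pseudogenome()` applies primitive SNP/INS/DEL records (loaded from
VCF by `load_variants()`) to the reference. Primitivity means one
reference-anchored event per record; multi-allelic rows are split and
anything non-primitive is dropped and counted. Overlapping records follow
a *first-wins* policy — deterministic and auditable, since upstream
variant callers do occasionally emit overlapping decomposed records.

Coordinates are 0-based half-open everywhere inside the package; VCF
positions are converted on load, bedGraph/BED output is 0-based.

The lift map is a block list per chromosome. SNPs do not break blocks
(substitution preserves coordinates); each indel ends a `MATCH` block.
Insertions become `INSERTED` blocks carrying a single reference anchor:
the last reference base at or left of the insertion (−1 at a contig
start). `lift_interval()` returns the smallest reference interval
covering the images of a query's matched bases and flags queries that
touch inserted sequence or span a deletion; a query wholly inside an
insertion returns the zero-length interval at its anchor. This mirrors
what projecting variant-strain alignments onto the reference requires:
never invent reference bases, but keep the information that some were
strain-specific.

Correctness is checked three ways in the test suite: exact ref to pseudo
to ref round trips on seeded genomes, exact length/base-identity
conservation laws, and equality with an independent Needleman–Wunsch
oracle (`Biostrings::pairwiseAlignment`, quadratic time) on 2-kb contigs,
asserted through optimal-score equality — robust to the tie ambiguity of
equivalent gap placements in repeats.

# Allelic classification

Reads are mapped (outside this package) to the diploid genome, where the
two haplotypes compete: a read carrying a strain allele aligns better to
its own haplotype, while a read from variant-free sequence maps equally
well to both and receives a low MAPQ from the aligner. Classification
therefore reduces to the mapped contig's strain suffix plus the standard
filters (`-f 2 -q 20` style; MAPQ 10 for 4C mates). The aligner-reported
MAPQ is trusted, never recomputed; filtered reads keep a reason code.
A `CrossOrientation` translates haplotype into parent, so the reciprocal
cross is one `swap_cross()` away, and label equivariance under that swap
is exact by construction (and asserted in tests).

# Coverage dialect

`binned_coverage()` follows the common browser-track dialect: a read
overlapping k bins counts once in each (not fractionally), the final
truncated bin keeps the nominal bin size in its RPKM denominator, and
5'-end extension (default 200 bp for ChIP-style tracks) happens before
binning. Strand splitting implements fr-firststrand: a fragment is
"forward" when read 2 maps to `+`, and each fragment is counted once via
its read 1. Spike-in scaling is `constant / spikein_reads`; the constant
is a free shared choice, only between-sample ratios matter.

# The allelic 4C model

A 4C library reports, for one bait ("viewpoint"), the genomic sites
ligated to it. Because of the primer design the viewpoint-proximal mate
covers a strain SNP inside the bait: its base assigns each pair to the
maternal or paternal bait allele (`demultiplex_viewpoint_pairs()`), and
pairs with an off-bait, low-MAPQ or third-allele viewpoint mate are
discarded with counts. Valid ligation products start exactly at a
restriction-fragment boundary, so `count_fragends()` keeps a plus-strand
alignment only if its start is a fragment's left boundary and a
minus-strand alignment only if its end is a right boundary — an exact
filter checked against a brute-force oracle in the tests. The two
fragends flanking the bait fragment carry self-ligation and undigested
template and are excluded from normalization and testing by default.

Tracks are reads-per-million of informative reads per allele and
replicate (so maternal and paternal tracks compare *shape*, not library
depth; a combined denominator is available as an option), smoothed by a
centered running mean over `k = 8` consecutive fragends — the same `k`
as the domain caller, one fewer free parameter. The ratio track is
`log2((mat + 1) / (pat + 1))` in rpm units: 0 where both alleles are
empty, antisymmetric under allele swap.

## Near-bait domain calling

Windows of `k = 8` consecutive fragends within ±1 Mb of the bait are
tested against a smooth distance-decay background: ordinary least
squares of `log(window rpm + 1)` on `log(window distance)`, then a
one-sided Poisson test of each window's count against its fitted
expectation, BH-corrected at 0.05; adjacent flagged windows merge into
domains. The window distance is the *harmonic* mean of its fragends'
distances to the bait: under inverse-power contact decay a window's mass
is dominated by its nearest fragends, and the harmonic mean is the
aggregation under which the window-level decay stays log-log linear.
(With a geometric or arithmetic mean the nearest windows sit
systematically above the fitted line and tilt it, which produces false
domains at both ends of the distance range.) This caller is a
deliberately simple, fully specified replacement for adaptive-window 4C
callers, not a reproduction of one.

## The paired differential test

Each replicate contributes a paired (maternal, paternal) count per
window, both measured in the same library. The null is the library-wide
allele balance `sum(m) / sum(m + p)` over all windows, not 0.5 — bait
allele recovery is rarely perfectly balanced. Counts are modeled
beta-binomially; a single intra-class correlation is estimated by method
of moments from the between-replicate variability within windows and
floored at zero, where the test reduces to the exact binomial test
(verified against `binom.test`). With two replicates — the realistic
design here — anything richer than a moment estimate is unjustifiable.
Two-sided p values use the minimum-likelihood rule, BH correction runs
across windows, and significance is adjusted p < 0.05.

# What the generator emulates, and what it does not

The synthetic module draws uniform-random contigs and plants strain
variants at one SNP per 150 bp and one indel (≤ 6 bp) per 1,500 bp —
the divergence scale of distant inbred mouse strains. Allelic read sets
draw paired 300-bp fragments (100-bp reads) from gene models with a
programmed maternal fraction; fragments overlapping no variant get
MAPQ 0, emulating ambiguous diploid mapping, so the simulator stands in
for the aligner without requiring one. 4C libraries draw interacting
fragends with probability proportional to `distance^(-alpha)` (alpha = 1)
times an allele-specific loop multiplier; a loop anchor spans 8
consecutive fragends (a CTCF-bound fragment run, roughly 2 kb) and the
default test configuration places it about 100 kb from the bait — the
promoter-to-imprinting-control-region span scale of a typical imprinted
domain — with 5,000 informative reads per allele and 2 replicates on a
420-kb contig (about 200 near-bait windows).

Simulated data are clean in ways real data are not: no mapping bias
beyond the MAPQ-0 surrogate, no PCR duplicates, no chimeric or partially
digested 4C products, no base-quality structure (sequencing errors
default to 0 so oracle tests are exact, with a 0.1% option). Passing
tests therefore certify the *computational* contracts — coordinate
arithmetic, counting exactness, calibration under the stated model — not
robustness to every artifact of real libraries.

# Numerical choices and known limitations

- Overlapping variants: first-wins with counts, as above.
- Insertions lift to a flagged zero-length anchor interval; reads wholly
  inside insertions are kept but flagged, reads across deletions get the
  covering interval plus a flag.
- RPKM keeps the nominal bin width at the chromosome-end bin.
- The rpm denominator is per-allele informative reads; `rpm` tracks sum
  to one million per allele and replicate by construction.
- The beta-binomial moment estimator needs at least two replicates with
  both alleles observed; otherwise it returns 0 (binomial).
- The Poisson background of the domain caller inherits a small downward
  Jensen bias from fitting on the log scale at low counts, so it is
  mildly anti-conservative: in the null simulation a small minority of
  seeded runs (about 1 in 10) yield one spurious domain. The paired
  differential test, by contrast, is conservative (empirical null
  fraction of significant windows far below 0.05).
- Problem sizes in the shipped tests — 10-kb genomes for liftover, 2-kb
  contigs for the alignment oracle, a 420-kb 4C contig, 25 seeds for
  stochastic properties — were chosen so the whole suite runs in about a
  minute while keeping every concentration bound meaningful.

# A worked 4C run

```{r}
library(allelome)

ref <- simulate_reference(c(chr4C = 420000L), seed = 5)
vs  <- simulate_strain_variants(ref, seed = 5)
bait <- 210000L
snp <- vs[vs$kind == "SNP" & abs(vs$pos - bait) < 2000, ][1, ]
vp <- viewpoint_spec("chr4C", snp$pos - 30, snp$pos + 30, snp$pos,
                     snp_maternal = snp$ref, snp_paternal = snp$alt)

fm <- digest_genome(ref)
win <- window_fragends(fm, "chr4C", bait, k = 8)
anchor <- win$start[which.min(abs(win$start - (bait + 1e5)))]
sim <- simulate_4c_experiment(ref, "chr4C", bait, vp,
                              anchors = data.frame(pos = anchor,
                                                   maternal_mult = 5,
                                                   paternal_mult = 1),
                              n_reads = 5000, replicates = 2, seed = 1)

res <- fourc_run(sim$pairs, sim$interacting, vp, sim$fragmap,
                 "chr4C", bait)
subset(res$differential, significant)
res$domains$maternal$domains
```
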