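Package: allelome
Title: Allele-Specific Genomics for F1 Hybrids: Diploid Genomes, Allelic
    Tracks and Allelic 4C-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for allele-specific analysis of sequencing data from F1
    hybrid crosses between inbred strains. Builds the three alignment targets
    used in hybrid designs (an N-masked reference, a strain pseudogenome with
    SNPs and indels applied, and a diploid genome carrying both haplotypes)
    together with an indel-aware coordinate lift map back to the reference;
    classifies alignments on the diploid genome into maternal, paternal or
    unassigned reads and summarizes allelic ratios at strain SNPs; produces
    RPKM-binned, strand-split and spike-in-scaled coverage tracks; and
    implements an allelic 4C-seq workflow (viewpoint-allele demultiplexing,
    in silico restriction digestion, exact fragment-end counting, smoothed
    rpm tracks, near-bait interaction-domain calling, and a paired
    maternal-versus-paternal beta-binomial differential test). A synthetic
    data module generates references, strain variants, allelic read sets and
    4C libraries with known ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
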