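Package: snepscan
Title: Single-Nucleosome Epi-Polymorphism Detection Between Yeast Strains
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for comparative epigenomics of closely related
    genomes at single-nucleosome resolution.  From aligned MNase-seq and
    MNase-ChIP-seq read starts in two or more strains, the package builds
    cross-strain coordinate maps from pairwise alignment blocks, calls and
    matches nucleosomes, detects single-nucleosome epi-polymorphisms
    (SNEPs) with a negative-binomial interaction test, quantifies
    gene-level epigenomic divergence (epidiv), scans segregant panels for
    loci controlling profile redistribution, and characterizes regionality
    and co-variation of histone marks.  A synthetic-data module generates
    genomes, nucleosome landscapes, read files and segregant crosses with
    known ground truth so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
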