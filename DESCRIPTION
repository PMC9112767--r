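Package: mitovar
Title: Mitochondrial DNA Copy Number and Heteroplasmy from Whole-Genome
    Sequencing Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained toolkit for mitochondrial genetics from
    short-read whole-genome sequencing: extracts candidate mitochondrial
    reads (chrM, NUMT read sinks, unmapped mates), remaps them to a
    circularized mitochondrial reference with a seeded banded aligner,
    calls heteroplasmic and homoplasmic variants with strand-aware
    frequency thresholds, rebuilds each sample's consensus mitochondrial
    genome and re-calls variants against it with coordinate liftover back
    to reference space, annotates calls against region and site tracks
    (hypervariable, homopolymer, hotspot, haplogroup, NUMT, dbSNP),
    estimates mitochondrial DNA copy number under three genome-coverage
    conventions, and ships a paired-end read simulator with truth sets so
    every stage is benchmarkable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
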