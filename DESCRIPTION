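Package: mitotandem
Title: Tandem Gene Pairs, Conserved Clusters and Repeats in Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of annotated plant mitochondrial genomes:
    reads GenBank or GFF3+FASTA records into a normalized feature model,
    detects tandem (ring-adjacent) gene pairs and shared colinear or inverted
    gene-order blocks on circular genomes, identifies conserved gene families
    and conserved tandem pairs across a genome panel, classifies species by
    pair-arrangement profiles and checks concordance with a phylogeny,
    analyses the tandem structure of the nad (complex I) gene family,
    detects perfect and compound microsatellites and forward/palindromic
    dispersed repeats under a fixed-pair Hamming model, and summarizes
    externally predicted C-to-U RNA-editing sites. Includes a seeded
    synthetic-panel generator with a machine-readable truth set for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
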