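Package: hydratx
Title: Hybrid Transcriptome Assembly Preprocessing, Redundancy Metrics and
    Orthology for Illumina-454 RNAseq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the computational stages of a
    hybrid Illumina-454 de novo transcriptome project in low-GC invertebrates
    such as Hydra: read cleaning (barcode stripping, adapter and trans-spliced
    leader removal, 3' homopolymer and quality filters), preparation of
    short-read contigs for co-assembly with long reads (duplication, chopping
    into 1999-nt overlapping segments, artificial quality synthesis),
    six-frame translation and longest-ORF extraction, protein-level
    redundancy removal with a six-criterion discard filter, the redundancy
    index and gene-number estimator, dataset comparison (RNAseq-only and
    predicted-only sets, sequential contaminant screening, genome support,
    pseudogene classification), reciprocal-best-hit orthology, and read
    subsampling saturation analysis.  All alignment steps run on an internal
    seed-and-extend local aligner with banded affine-gap dynamic programming.
    A seeded synthetic-data generator emulates every input with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
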