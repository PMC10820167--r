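Package: mybscan
Title: MYB Transcription-Factor Family Census, Phylogeny and Drought-Response Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects MYB DNA-binding repeats in plant protein sequences with a
    position-specific log-odds profile calibrated against an explicit null model,
    applies the field's identification rules (E-value threshold, conserved
    tryptophan requirement, GFF-based isoform de-duplication), classifies members
    into 1R/R-R/2R/3R/4R/5R subfamilies by repeat count and inter-repeat spacing,
    tabulates per-species family composition, builds neighbor-joining phylogenies
    with bootstrap support for multi-repeat members, and screens family members for
    drought-responsive differential expression with a negative-binomial Wald test.
    Ships a synthetic proteome and count-matrix generator with machine-readable
    truth tables so the whole pipeline is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    rtracklayer,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    DESeq2,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
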