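Package: bitome
Title: Binary Genome Feature Matrices and Derived Genomic Statistics
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digitizes an annotated bacterial genome into a sparse binary
    feature-by-position matrix (a "bitome"): every genomic position is
    associated with the features it encodes (nucleobases, codons, amino
    acids, genes, transcription units, promoter elements, regulator
    binding sites, regulons and more), with gene-like tracks split by
    strand and reading frame to keep the matrix binary. Provides the
    derived statistics of that representation (per-position bit counts,
    sequence coverage, bit density, moving-window density profiles, UTR
    lengths, promoter element geometry, inter-transcription-unit
    regions, sliding-window RNA folding scores), mapping of adaptive-
    evolution SNP tables onto the matrix with rank-based enrichment
    tests, and a class-imbalance-aware gene classification harness
    (lockbox holdout, majority downsampling, repeated cross-validation,
    shuffled-label controls, L1-regularized linear models with
    coefficient-based feature importance). A synthetic annotation
    generator emulates all required input formats so the full workflow
    is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    IRanges,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    glmnet,
    yaml,
    stats,
    utils,
    methods
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
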