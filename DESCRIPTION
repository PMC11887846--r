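Package: pbrisk
Title: Pseudobulk Multi-Omic Differential Testing Across Diagnosis and
    Polygenic Risk Extremes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential analysis of single-nucleus RNA-seq and ATAC-seq
    data aggregated to pseudobulk, contrasting psychiatric diagnosis and
    matched extreme polygenic-risk groups. Provides nucleus-level quality
    control, pseudobulk aggregation, distance-weighted gene-activity
    scores from chromatin peaks, data-driven covariate selection with a
    hidden-noise principal component, negative-binomial and linear Wald
    tests with Benjamini-Hochberg correction, propensity-score matching
    of high- versus low-risk donors with exact sex matching,
    hypergeometric pathway and transcription-factor motif
    over-representation, Spearman correlation networks across omics
    layers, and a seeded synthetic-cohort generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
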