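Package: paracomp
Title: Detecting Proteomic Compensation and Collateral Loss Between Paralogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering proteomic compensation and collateral
    loss between paralogous genes. Supports two study designs: isogenic
    knockout proteomes (label-free quantification preprocessing, knockout
    verification, and paralog-response testing) and matched tumour cohorts
    with copy-number, transcriptome, and proteome layers (pair filtering,
    hemizygous-loss calling and validation, covariate-adjusted
    loss-response regression with Benjamini-Hochberg hit calling, protein
    residualization to isolate post-transcriptional signal, and mechanism
    classification). Downstream analyses cover interaction-network pair
    features, enrichment batteries, and L1-penalized predictive modeling.
    A synthetic cohort generator with planted ground truth makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    glmnet,
    igraph,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
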