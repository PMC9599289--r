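Package: exomir
Title: Exosomal miRNA Biomarker Panels and Censored RT-qPCR Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing and evaluating exosomal miRNA biomarker
    panels for pancreatic ductal adenocarcinoma (PDAC) and for quantifying
    them by RT-qPCR. Covers copy-number-alteration frequency filtering and
    patient-coverage panel optimization on patient-by-gene alteration
    matrices, stage-stratified alteration sets, offline gene annotation
    (exosomal presence, disease-contrast expression direction, gene to
    mature-arm expansion, miRNA nomenclature), a censored delta-delta-Cq
    quantification engine with non-detect imputation, dual-control
    normalization, significance tiers and 5p/3p arm-preference analysis,
    plus synthetic-data generators with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
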