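Package: igcomp
Title: Integrative Genome Comparison of Tumor Copy-Number and Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for comparing somatic copy-number landscapes
    of two tumor cohorts (e.g. primary versus metastatic melanoma) and
    integrating them with expression data. Implements circular binary
    segmentation of array-CGH log2-ratio profiles, tallest-mode centering and
    data-driven gain/loss thresholds, minimal common region (MCR) delineation,
    consensus non-negative matrix factorization subclassing with cophenetic
    rank selection, per-reduced-segment Fisher exact comparison with Storey
    q-value FDR control, region-of-interest merging, and SAM-based selection of
    dosage-driven candidate genes. Ships a truth-tracked synthetic-cohort
    generator so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
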