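Package: germsoma
Title: Germline Influence on Somatic Alteration Patterns in Multi-Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to test whether germline background shapes the somatic
    alterations found in independent tumors of the same patient. Provides a
    synthetic-cohort simulator with known ground truth; array-CGH profile
    handling with normalization, circular binary segmentation, MAD-based
    quality control and merged-level gain/loss calling; within- versus
    between-patient concordance tests on chromosome arms and genome-wide
    with intraclass-correlation estimation; allelic-imbalance ratio
    computation and classification for microsatellite and SNP peak data; and
    a Bayes-factor plus Wilcoxon procedure for detecting preferential
    (allele-specific) imbalance across a patient's tumors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    dplyr,
    generics,
    MASS,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
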