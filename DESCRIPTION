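Package: edisonr
Title: Epigenetic Stratification of Glioma Immunosuppressive State
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Derives a binary immune-evasion label (EDISON) for glioma cases
    from immune-composition scores, selects informative CpG methylation
    probes with variance-based independent filtering, expert gene panels and
    shadow-feature (Boruta-style) selection, trains and compares
    random-forest and multilayer-perceptron classifiers of the label from
    methylation beta values, and validates the label's prognostic value with
    Kaplan-Meier, log-rank and univariate Cox analyses. Includes a
    synthetic-cohort generator that emulates the joint structure of
    methylation, expression, immune scores and survival so that the full
    pipeline is testable without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
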