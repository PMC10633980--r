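Package: mrflow
Title: Two-Sample Mendelian Randomization Screening, Mediation and
    Genetic Risk Score Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for two-sample Mendelian
    randomization (MR) studies of many exposures against a common
    outcome, as used for microbiome-wide causal screens of disease
    risk. Provides instrument selection from GWAS summary statistics
    (p-value and allele-frequency filters, greedy LD clumping, proxy
    substitution, F-statistics), allele harmonization with
    frequency-based resolution of palindromic variants, a battery of
    causal estimators (Wald ratio, inverse-variance weighted, MR-Egger,
    weighted median, mode-based) with Cochran's Q heterogeneity and
    MR-PRESSO outlier diagnostics, Benjamini-Hochberg screening across
    taxa, two-step MR mediation with multivariable MR and bootstrap
    uncertainty, and a weighted genetic risk score survival stage under
    Cox proportional hazards. A seeded synthetic-data generator
    produces every input with known ground truth for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
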