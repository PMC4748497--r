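Package: ocmrisk
Title: Comorbidity-Adjusted Other-Cause Mortality Prediction for Localized Prostate Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a localized prostate cancer patient's risk of death from
    causes other than prostate cancer at 10 and 15 years, combining an
    age-shifted Social Security Administration life table with multiplicative
    odds-ratio adjustment for fourteen comorbidities derived from an actuarial
    life-expectancy model. Includes conditional-probability adjustment of
    untreated prostate-cancer mortality for competing other-cause death,
    Gleason regrading deconvolution of historical risk tables, validation
    tools (Harrell's concordance index for censored data, horizon-specific
    Kaplan-Meier calibration curves), and a reproducible synthetic-cohort
    generator for end-to-end testing of the validation pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
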