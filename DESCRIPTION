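Package: evidsat
Title: Theme Emergence and Saturation Modelling for Early-Adoption Clinical Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how descriptive evidence themes (device
    utilities and operational issues) emerge and saturate in an early-adoption
    clinical literature corpus. Builds article-by-theme binary presence
    matrices, assesses inter-rater coding reliability (agreement rate and
    Cohen's kappa with Landis-Koch interpretation), derives cumulative
    theme-occurrence series under the first-occurrence rule, fits exponential
    and logistic saturation curves by nonlinear least squares with AICc-based
    model comparison, inverts fitted curves to estimate the time or
    publication count needed to reach target proportions with confidence
    intervals, and validates the estimation pipeline with a seeded synthetic
    corpus generator and parameter-recovery harness. Ships the da Vinci
    early-adoption corpus (19 articles x 16 themes, 2001-2004) as a built-in
    dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
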