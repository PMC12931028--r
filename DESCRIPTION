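Package: mlsurvstd
Title: Standardized Survival Probabilities for Multilevel Survival Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits three-level proportional-hazards survival models with a
    Weibull baseline and nested normal random intercepts (patients within
    surgeons within centers) by maximum likelihood with nested adaptive
    Gauss-Hermite quadrature. Predicts cluster effects by empirical Bayes
    (posterior means and modes with posterior standard deviations), computes
    directly standardized survival probabilities that fix or marginalize each
    hierarchical level, contrasts between hierarchical units with
    parametric Monte-Carlo percentile confidence intervals, median
    hazard ratios, and cluster rankings for provider profiling. Includes a
    synthetic-data generator for three-level survival data and a pipeline
    driver with a command-line entry point.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    optparse,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    flexsurv,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
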