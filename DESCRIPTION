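Package: glybench
Title: Benchmarking Neural Network Forecasters of Blood Glucose
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end benchmark for short-term blood-glucose forecasting
    from continuous glucose monitoring (CGM) data. Provides a seeded synthetic
    CGM cohort generator, the common preprocessing pipeline (cubic-spline gap
    filling, feature scaling, supervised windowing), a catalog of ten published
    recurrent/convolutional forecasting architectures plus two averaging
    ensembles backed by a compact batched neural-network engine, a uniform
    training protocol, the standard seven-metric evaluation suite, Parkes
    (consensus) error-grid clinical scoring, and three loss-based model
    comparison procedures: Bayesian Plackett-Luce ranking, the Model Confidence
    Set, and the Superior Predictive Ability test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
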