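Package: pinyon
Title: Nonparametric Multiplicative Regression for Climate Niche Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kernel-smoothed climate niche models for presence/absence data
    using nonparametric multiplicative regression (NPMR): multiplicative
    Gaussian weighting with a leave-one-out local mean estimator, forward
    free-search model selection under cross-validated log-likelihood (logB)
    improvement rules, model evaluation (AUC, cross-validated R-squared,
    predictor sensitivity, residual diagnostics), derivation of bioclimatic
    predictors from monthly climate normals, probability-of-occurrence
    mapping over gridded climate, and last-glacial-maximum hindcasting via
    predictor substitution. Includes a virtual-species generator producing
    synthetic climate surfaces and occurrence datasets with known niche
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
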