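Package: teletmle
Title: Targeted Learning of Consultation-Mode Effects on Antibiotic Prescribing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the causal effect of remote versus
    face-to-face primary-care consultations on antibiotic prescribing for
    acute respiratory infections. Provides a synthetic electronic health
    record generator with known ground truth, consultation-episode cohort
    construction, covariate engineering, covariate-balance and positivity
    diagnostics, a practice-clustered cross-validated superlearner with a
    non-negative-least-squares metalearner, and targeted maximum likelihood
    estimation of the average treatment effect and marginal odds ratio with
    influence-curve inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    glmnet,
    jsonlite,
    mgcv,
    pracma,
    purrr,
    ranger,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
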