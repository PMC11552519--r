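Package: classifyrefine
Title: Classify-Refine Models of Social Attribution in the Iterated Dictator Game
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modelling and model comparison for repeated Dictator
    ("Sharing Game") tasks in which participants report fairness expectations
    and attributions of harmful intent (HI) and self-interest (SI) about each
    dictator. Implements the classify-refine agent (two refineable states per
    attribution dimension with Dirichlet outcome-likelihood learning,
    trial-to-trial forgetting and dictator-to-dictator carry-over) and a
    classic fine-grained (6x6 fixed grid) Bayesian learner, softmax report
    channels with an ethnicity bias term, maximum-a-posteriori fitting by
    adaptive multistart coordinate grid search, small-sample-corrected BIC/AIC
    model comparison, a synthetic two-wave placebo/citalopram cohort generator
    with parameter- and model-recovery experiments, and the second-level
    statistics layer (robust stability regressions, Cook's-distance outlier
    screening, wave-by-drug mixed-effects models).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    stats,
    utils,
    MASS,
    lme4,
    lmerTest,
    generics,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
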