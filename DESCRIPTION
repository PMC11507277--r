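Package: posturestack
Title: Stacked Ensemble Classification of Sleep Posture from Airbag
    Pressure Mattresses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies sleep posture (supine, side, fetus, prone) from the
    four airbag pressure channels of a smart mattress. Implements the full
    enhanced-stacking workflow: statistical feature augmentation of the raw
    pressure channels, a from-scratch differentiable deep neural decision
    tree (soft binning with Kronecker-product leaf routing), a zoo of
    candidate classifiers with a shared estimator contract, Gaussian-process
    Bayesian hyperparameter optimization, entropy-weight composite scoring
    for base-model selection, five-fold out-of-fold stacking with a
    multinomial logistic meta-learner, five-metric evaluation with Cohen's
    kappa, and permutation-based feature-importance reporting. A seeded
    synthetic-data generator emulates class-conditional airbag pressure
    distributions so the whole pipeline is testable without access to
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    ranger,
    xgboost,
    nnet,
    glmnet,
    kernlab,
    lhs
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
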