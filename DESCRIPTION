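Package: fadel
Title: Feature-Type-Aware Discretization Ensemble Learning for Imbalanced
    Binary Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-layer stacked ensemble for extremely imbalanced binary
    classification on heterogeneous clinical-like tabular data. Continuous
    features are discretized by supervised CART threshold extraction under
    depth and leaf-count budgets; raw and discretized feature views are
    routed to type-compatible base learners (gradient-boosted trees on the
    raw view, ordered-target-encoded boosting and AdaBoost on the interval
    view), and a random-forest meta-model fuses the four base-learner
    probabilities by majority voting. Includes imbalance-aware evaluation
    (sensitivity, specificity, G-mean, ROC/PR curves), Fisher-Pearson
    skewness diagnostics, a seeded generator of imbalanced skewed tabular
    datasets, and a command-line interface for the full fit/predict/evaluate
    lifecycle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    e1071,
    pROC,
    ranger,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
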