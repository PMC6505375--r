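Package: raterstack
Title: Rater-Adaptive Ensembles for Crowdsourced Developmental Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for aggregating crowdsourced behavioral annotations of
    children into developmental-delay screening decisions. One classifier is
    trained per rater and the per-rater predictions are combined with softmax
    weights over validation-accuracy deltas against a majority-vote baseline.
    A two-layer stacked pipeline first separates typical from atypical
    development and then autism spectrum disorder from other speech and
    language conditions, with three-fold cross-validated metric reporting.
    Per-feature Shapley attributions are propagated through the ensemble
    weights and summarized into global feature rankings, and an elastic-net
    logistic regression module supports cross-site transfer analyses with
    feature-selection frequency tables. A synthetic annotation simulator with
    heterogeneous, feature-specific rater reliability makes every stage
    testable without access to clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
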