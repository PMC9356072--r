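Package: sauronrf
Title: Simultaneous Regression and Classification Random Forests for Drug
    Sensitivity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint regression and classification random forests (SAURON-RF)
    for predicting continuous drug sensitivity (log IC50) together with a
    binary sensitive/resistant call from gene expression, with explicit
    countermeasures against class and regression imbalance: simple and
    distance-based sample weights, minority-class upsampling and proportional
    upsampling, and class-aware tree-weighting schemes (binary, binary
    sensitive, majority, majority sensitive). Includes the conventional
    regression and classification forest baselines, a hierarchical
    classify-then-regress baseline, greedy minimum-redundancy
    maximum-relevance (mRMR) feature selection by mutual information, an
    evaluation workflow with train/test splitting and cross-validated
    hyperparameter selection, and a synthetic-data generator emulating
    imbalanced cell-line drug-response panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    rlang,
    tibble,
    dplyr,
    readr,
    withr,
    generics,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
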