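Package: hollowtree
Title: Directional Feature Importance for Boosted Tree Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Additive decomposition of single decision trees and gradient
    boosted tree ensembles into per-prediction, per-feature contributions
    (probability space for trees, log-odds space for ensembles), and the
    Hollow-tree Super (HOTS) procedure that aggregates contributions from
    confident, correct predictions across stratified cross-validation folds
    into signed, magnitude-comparable per-class feature importances. Includes
    deterministic CART and Newton gradient-boosting trainers, an importer for
    the common boosted-model JSON dump dialect, and the three baseline
    importance methods used for comparison: Gini importance, permutation
    importance and one- or two-dimensional partial dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    pROC,
    yaml
Config/testthat/edition: 3
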