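Package: hfensemble
Title: Imbalance-Aware Hybrid Ensembles for Heart Failure Mortality Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting heart-failure mortality from routine clinical
    records under heavy class imbalance. Implements a hybrid resampler that
    combines boosting-derived minority emphasis weights, weight-biased SMOTE
    synthesis and Tomek-link cleaning; a hybrid classifier that bags the
    empirically best conventional learner and soft-votes it with itself;
    dual feature ranking by tree-ensemble impurity importance and information
    gain; a multi-split evaluation protocol with Wilcoxon signed-rank
    comparisons; and partial-dependence extraction of high-risk value ranges.
    A schema-aware synthetic generator emulating a heart-failure clinical
    records table makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
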