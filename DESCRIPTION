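Package: stageminer
Title: Stage-Discriminative Feature Discovery from Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A nested cross-validated filter/wrapper feature-selection and
    rule-mining pipeline for two-class (early versus late tumor stage)
    expression matrices. Features are first ranked per inner training fold by
    a two-group t-test or one-way ANOVA F filter, then a binary particle
    swarm optimization wrapper searches feature subsets by minimizing an
    AUC-based fitness evaluated with a radial-kernel support vector machine
    on inner validation folds. The discrimination power of the selected
    features is reported for a suite of classifiers (accuracy, AUC-ROC,
    per-class F1, MCC, sensitivity, specificity), and FP-Growth association
    rule mining on discretized (low/medium/high) expression identifies
    stage-associated features ranked by their repeat count in stage-consequent
    rules. A synthetic-data generator with planted differential features makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    randomForest,
    xgboost,
    class,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
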