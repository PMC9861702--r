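Package: demlr
Title: Ensemble-Based Multi-Task Learning for Drug Combination Synergy
    and Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint prediction of five drug-combination synergy scores
    (Loewe, Bliss, ZIP, HSA, S), a binary synergy label and a binary
    adverse drug-drug-interaction label from drug chemical descriptors
    and cell-line gene-expression profiles. Implements a multi-task
    neural network with a hybrid ensemble layer of three expert types
    (dense, bi-additive, bi-interaction), per-task gating networks for
    task-specific fusion, label-smoothing cross-entropy, order-augmented
    training with early stopping, five-fold cross-validation, ablation
    variants, regression/classification metric suites, score-consistency
    analysis and candidate-screening rules, together with a synthetic
    cohort generator for desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
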