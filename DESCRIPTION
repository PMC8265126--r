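Package: d2tra
Title: Identification and Prediction of Difficult-to-Treat Rheumatoid
    Arthritis in Routine Care Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to identify and predict difficult-to-treat rheumatoid
    arthritis (D2T RA) patients from routine-care electronic health record
    data. Implements a rule-based classifier applying the first two EULAR
    D2T RA criteria to structured prescription and disease-activity data, a
    surrogate model approximating the DAS28-ESR where components are
    missing, a lexicon-driven text miner for clinical letters with
    negation-aware active-disease detection, time-aggregated feature
    engineering with FDR filtering and bootstrapped L1-penalized logistic
    regression for feature importance, gradient-boosted identification and
    pre-biological prediction models on monthly forward-filled timelines,
    and a supervised two-dimensional embedding of longitudinal hematology.
    A synthetic EHR generator with planted ground truth emulates the
    routine-care source so every step is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    glmnet,
    xgboost,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
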