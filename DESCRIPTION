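Package: fesresponder
Title: Predicting Muscle Response to FES Therapy from Baseline Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for predicting whether an upper-extremity muscle will
    respond to functional electrical stimulation (FES) therapy after cervical
    spinal cord injury, from baseline surface electromyography (sEMG).
    Includes a synthetic-cohort simulator with planted responder structure,
    sEMG preprocessing and steady-state segment extraction, a 24-feature
    time/frequency-domain feature bank, Kendall-tau responder labeling from
    longitudinal manual muscle testing scores, curated feature sets
    (Hudgins, MD, PCA, forward selection, clinical variables), classifier
    evaluation under leave-one-participant-out cross-validation with
    trial-vote aggregation, and an imbalanced-class metric suite (MCC,
    macro F1) with analytic chance baselines and confusion-matrix
    reconstruction from printed metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    e1071,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
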