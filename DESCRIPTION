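Package: persense
Title: Passive Smartphone and Wearable Sensing Pipeline for Daily
    Symptom-Burden Prediction in Perioperative Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for turning raw smartphone and wearable sensor streams
    (accelerometer, activity recognition, GPS, screen, communication,
    battery, ambient light, conversation, per-minute heart rate and steps,
    sleep episodes) plus daily 10-symptom diaries into next-day high/low
    symptom-burden classifications.  Includes a synthetic perioperative
    cohort generator with configurable behavior-symptom coupling, day-level
    behavioral feature extraction, person-mean-centered outcome labeling,
    order-faithful cleaning and split-aware imputation, mutual-information
    feature selection, SVM-SMOTE minority resampling, temporal
    leave-one-day-out nested cross-validation with leaf-wise gradient
    boosting and non-sensor baselines, pooled classification metrics, and
    additive (SHAP) feature attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    e1071,
    geosphere,
    rpart,
    stats,
    utils,
    xgboost
Suggests:
    class,
    jsonlite,
    optparse,
    pROC,
    ranger,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
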