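Package: actisleep
Title: Actigraphy Sleep Scoring and Sleep-Quality Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based scoring of wrist-actigraphy activity counts into sleep
    periods (sleep onset and awakening via a candidate-row state machine,
    inferred bedtime and latency, wake after sleep onset, sleep efficiency,
    good/poor quality labels, nonwear handling), construction of labeled
    awake-activity/sleep-quality datasets, a suite of six sequence classifiers
    (logistic regression, multilayer perceptron, 1-D convolutional network,
    Elman recurrent network, LSTM, and a time-batched LSTM) trained with
    RMSprop and accuracy-based early stopping, confusion-matrix and ROC/AUC
    evaluation, and a synthetic actigraphy cohort generator with per-night
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
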