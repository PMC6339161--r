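Package: flowpick
Title: Emotion and Engagement Prediction for Order Picking from Wearable Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for predicting the affective state
    (pleasantness, arousal) and task engagement of warehouse order-picking
    workers from wearable sensor streams. Provides a synthetic-data generator
    with known latent flow/affect states (pulse waves carrying LF/HF heart-rate
    variability, joint rotation and inertial movement streams, eye-tracker
    pupil/blink/gaze signals, order-sheet manifests), a time-series feature
    battery (sliding-window HRV band powers, spectral-grid features, a
    peak-valley extremum operator, sample entropy and largest Lyapunov
    exponents, task-complexity encoding), Brunner-Munzel rank-test feature
    screening, a feedforward rectifier network regressor with layer-wise
    autoencoder pretraining and weight-based variable importance, and
    leave-one-subject-out / leave-one-session-out cross-validation evaluated
    with a scale-normalized error metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
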