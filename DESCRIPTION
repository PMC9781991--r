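Package: emgselect
Title: Wrapper Feature Selection and SVM Classification for Surface EMG
    Movement Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying limb movements from multi-channel
    surface electromyography (EMG). Implements digital Butterworth
    band-pass preprocessing, overlapping-window segmentation, the 26
    classical time-domain predictors (MAV, RMS, WL, ZC, WAMP, sample
    entropy, Higuchi fractal dimension, ...), one-way ANOVA predictor
    prescreening, one-vs-all soft-margin SVM classification with
    stratified k-fold cross-validation, and wrapper feature selection by
    a binary genetic algorithm and by binary particle swarm optimization
    with a sigmoid transfer function, both minimizing the cross-validated
    mean classification error. Includes a seeded synthetic-EMG database
    generator, per-class confusion-matrix metrics (accuracy, sensitivity,
    specificity and their mean, the efficiency), leave-one-feature-out
    sensitivity analysis, and a config-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
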