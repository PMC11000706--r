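Package: seizunit
Title: Hybrid Convolutional Recurrent Units for EEG Seizure Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of epileptic seizures from single-channel EEG using
    repeating 1D-convolution, bidirectional recurrent (LSTM or GRU) and
    average-pooling feature-extraction units feeding dense classifiers.
    Covers reading Bonn-layout plain-text EEG records, zero-phase Butterworth
    band-pass preprocessing, non-overlapping segmentation, a declarative
    registry of thirty published network configurations across six input
    regimes and five classification tasks, stratified five-fold
    cross-validated training and evaluation with accuracy, specificity,
    sensitivity and F1, and conv/recurrent layer-ablation experiments.
    Includes a seeded surrogate-EEG generator with class-distinct spectral
    and amplitude structure so the full pipeline runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
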