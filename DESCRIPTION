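Package: sacnn
Title: Self-Attention-Augmented Convolutional Encoding Models of V1 Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and trains a family of factorized convolutional encoding
    models of primary visual cortex neurons, from receptive-field-only models
    with a center-hypercolumn readout to fully contextual models augmented
    with a single-headed spatial self-attention layer. Provides stage-wise
    incremental training with weight inheritance and block freezing, peak
    tuning evaluation metrics alongside Pearson and noise-ceiling-normalized
    correlation, readout center/surround decomposition and gradient-based
    receptive-field attribution, and a synthetic V1 stimulus/response
    generator (Gabor-energy neurons with controllable surround modulation) so
    that every analysis runs at desk scale without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
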