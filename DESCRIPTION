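Package: octqrs
Title: Fetal QRS Detection from Abdominal ECG with 1-D Octave Convolution Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end detector of fetal QRS complexes in 4-channel
    non-invasive abdominal electrocardiograms. Implements 1-D octave
    convolutions that factorize feature maps into full- and half-resolution
    frequency groups, a residual convolutional trunk with a bidirectional
    GRU head emitting per-100-ms frame decisions, an analytic
    multiply-accumulate and feature-memory cost model, a 1-D Grad-CAM
    explainer for the trained detector, and a seedable synthetic
    fetal/maternal ECG simulator with ground-truth fetal R-peak
    annotations. All network computation (forward, backward, Adam
    training) is implemented in R and C++ with no external deep-learning
    framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
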