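Package: taskmo
Title: Task-Based Model Observers for Signal Detection in CT-Like Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Task-based image-quality assessment for CT-like images via model
    observers on binary signal-detection tasks. Generates synthetic
    background-known-statistically (BKS) ensembles with controllable noise
    correlation structure and parametric signals (signal-known-exactly nodule
    profiles and signal-known-statistically rotated elliptical profiles),
    estimates and applies the Hotelling observer in sample and
    known-covariance forms, trains supervised model observers (convolutional
    and single-layer neural networks) and a self-supervised observer built
    from a convolutional denoising autoencoder feeding an RBF-kernel support
    vector machine, and compares observers through ROC/AUC learning-curve
    experiments with a reproducible configuration-driven command line.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    e1071,
    jsonlite,
    yaml,
    tiff,
    lhs,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
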