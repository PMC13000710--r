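Package: specfuse
Title: Feature-Fused Spectral Classification for Laser-Induced Breakdown Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for classifying atomic emission spectra by sample origin.
    Provides a synthetic LIBS (laser-induced breakdown spectroscopy) spectrum
    simulator driven by elemental concentration profiles and an emission-line
    library; leakage-safe global min-max scaling with spectral-statistical
    feature fusion; a one-dimensional convolutional neural network trained
    from scratch alongside tuned shallow baselines (random forest, k-nearest
    neighbours, PLS-DA, gradient-boosted trees) with a Tree-structured Parzen
    Estimator hyperparameter search; dual interpretability through 1D
    Grad-CAM++ class activation maps and Shapley-value feature attribution;
    and evaluation utilities covering stratified splits, cross-validation,
    signal-to-noise-swept robustness testing, and unsupervised embedding
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    cluster,
    ranger,
    xgboost,
    mixOmics,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, class
Config/testthat/edition: 3
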