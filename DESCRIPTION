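Package: epimap
Title: Learned Electrocardiographic Imaging with Geometric Electrode Registration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reconstructs epicardial (heart-surface) potentials from
    body-surface electrograms with small neural networks, replacing the
    classical regularized inverse of electrocardiographic imaging (ECGi).
    Provides a geometric registration scheme that maps subject-specific
    torso electrode clouds onto a fixed 30x90 cylindrical raster and
    epicardial sock electrodes onto a normalized disk resampled at a fixed
    165-node template, so that one convolutional model can be trained and
    applied across subjects with different electrode layouts. Includes
    electrogram preprocessing (synchronized beat averaging, trailing moving
    mean, baseline alignment, bad-lead interpolation), natively implemented
    fully connected, LSTM and convolutional inverse solvers, evaluation
    metrics (per-lead electrogram correlation, activation-time maps from
    maximal negative dV/dt, pacing-site localization error), two
    leave-one-out cross-validation designs, and a synthetic paired
    torso/heart data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    interp,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
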