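Package: opticalbci
Title: CSP-LSTM Fusion Predictor for Motor-Imagery EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the OPTICAL predictor for motor-imagery (MI)
    electroencephalography (EEG) classification: common spatial pattern (CSP)
    filtering of whole trials reduced to one scalar by Fisher linear
    discriminant analysis, fused with the regression output of a small LSTM
    network trained on sliding-window CSP log-variance sequence features, and
    classified by a radial-basis-function support vector machine. Includes
    Bayesian optimization (Gaussian-process surrogate, expected improvement)
    of the LSTM learning rate and L2 penalty, a 10x10-fold cross-validation
    harness with misclassification, sensitivity, specificity and Cohen's
    kappa, a two-stage one-vs-rest cascade for three-class operation with a
    non-task class, and a seeded synthetic MI-EEG generator so the whole
    pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    Rcpp,
    e1071,
    ggplot2,
    lhs,
    signal,
    stats,
    rlang,
    tibble,
    utils
Suggests:
    MASS,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
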