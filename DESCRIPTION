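Package: pplsda
Title: Powered Partial Least Squares Discriminant Analysis with
    Prediction-Optimised Power Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-group classification of high-dimensional, log-scale expression
    matrices by partial least squares discriminant analysis (PLS-DA) and its
    powered variant (PPLS-DA), in which a power parameter gamma in [0,1] shifts
    the loading weights between the correlation part (gamma -> 1) and the
    standard-deviation part (gamma -> 0) of the covariance. Provides the
    classical per-component choice of gamma by canonical-correlation
    maximisation as well as a joint selection of gamma and the number of latent
    components by nested Monte-Carlo cross-validation minimising the prediction
    error of a linear discriminant analysis on the component scores. Includes
    an outer evaluation harness with balanced down-sampled splits, mean
    prediction errors with Student-t confidence intervals and CI-overlap
    significance calls, t-test-filtered LDA and linear SVM baselines, a
    generator for the five simulated two-class expression designs used to
    benchmark the methods, and covariance diagnostics (condition indexes,
    principal-component/class covariances).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
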