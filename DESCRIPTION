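Package: riembci
Title: Riemannian Tangent-Space Features and Discriminative Filter Banks
    for Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiclass motor-imagery EEG classification on the manifold of
    symmetric positive-definite matrices. Trials are represented by sample
    covariance matrices; the affine-invariant Riemannian metric supplies
    geodesic distances, Karcher means and tangent-space coordinates.
    Subject-specific discriminative frequency bands are screened with a
    distance-based one-way MANOVA pseudo-F statistic over a 2 Hz filter-bank
    grid, merged, and expanded into a multi-scale filter bank; tangent-space
    features from every time-frequency cell feed a cross-validated linear
    support vector machine. A seeded generator of motor-imagery-like EEG with
    planted class-dependent band power makes the whole pipeline testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    e1071,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vegan
Config/testthat/edition: 3
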