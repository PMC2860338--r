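Package: sparsart
Title: Sparsity-Constrained SART Reconstruction for Few-View Fan-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative image reconstruction from a limited number of fan-beam
    projections using a SART-type projected-gradient algorithm with an lp
    sparsity constraint (1 <= p <= 2) in an invertible transform domain.
    Provides an area-weighted fan-beam projector built by exact polygon
    clipping, a full-depth orthonormal 2D Haar sparsifier, shrinkage operators
    with adaptive lp-ball projection by dichotomy search, classical SART and
    ISTA reference steps, the modified Shepp-Logan phantom, and an experiment
    driver for few-view reconstruction studies with convergence logs as tidy
    tibbles.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tibble,
    generics,
    ggplot2,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
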