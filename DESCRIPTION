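Package: ringremap
Title: Ring-Attractor Remapping in Recurrent Networks Trained on
    Navigation and Context Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Trains vanilla (Elman) recurrent networks to integrate angular
    velocity on circular 1D/2D tracks while reporting a transiently cued
    discrete latent state, and characterizes the emergent population
    geometry and dynamics: position-binned tuning curves and synthetic
    sessions mimicking trialized recordings, Procrustes manifold alignment
    with rotation nulls, position subspaces and remapping dimensions,
    per-bin remapping vectors and their nullspace controls, numerical
    fixed-point identification with Jacobian stability classification, and
    single-unit rate- versus global-remapping scores. All inputs are
    generated internally; training uses hand-derived backpropagation
    through time with a sequence-length curriculum and gradient clipping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    rlang,
    utils,
    generics,
    ggplot2,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
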