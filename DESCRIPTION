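Package: shapecv
Title: Iterative Data-Driven Collective Variables from Shape-Based
    Gaussian Mixtures and Weighted Linear Discriminants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to discover and iteratively refine linear collective
    variables (CVs) for biased sampling of conformational transitions in
    particle systems.  Fits frame-weighted Gaussian mixture models on
    rigid-body-aligned Cartesian coordinates (shape-based GMM with Kronecker
    particle covariances), derives frame-weighted linear discriminant
    coordinates between two metastable states, matches refitted clusters to
    reference states by Bhattacharyya distance, and drives well-tempered
    metadynamics or on-the-fly probability enhanced sampling (OPES) bias
    bookkeeping along the learned coordinate, including free-energy-surface
    estimation, reweighting, and convergence diagnostics.  A built-in
    overdamped Langevin engine on Gaussian-mixture toy potentials provides
    exact oracles for end-to-end testing of the full refinement loop.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    ggplot2,
    generics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
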