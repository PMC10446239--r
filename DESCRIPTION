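Package: chrrt
Title: Coordinate Hit-and-Run with Rounding and Thinning for Uniform Flux Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Uniform sampling of convex flux polytopes of constraint-based
    metabolic models. Implements the full CHRRT workflow: polytope
    preprocessing (redundancy removal by linear programming, tightening of
    near-degenerate inequalities to equalities, null-space dimension
    reduction, Chebyshev centers), maximum-volume inscribed ellipsoid
    rounding, multi-chain coordinate hit-and-run sampling with
    fixed-frequency thinning and affine back-transformation to flux
    coordinates, split-chain rank-normalized effective-sample-size and R-hat
    convergence diagnostics, and an ESS-per-time benchmarking harness with
    ready-to-use thinning guidelines for simplices and genome-scale models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    xml2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
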