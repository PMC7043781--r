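Package: critnet
Title: Criticality and Scaling Analysis of Residue Contact Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Elastic-network normal mode analysis of protein native dynamics
    and of generated reference systems (fcc lattice clusters, cubic lattices,
    ideal polymer chains). Builds Gaussian-network Kirchhoff matrices and
    symmetric normalized graph Laplacians, computes mode spectra, residue
    fluctuation covariances, distance-dependent cross-correlation functions,
    correlation lengths and finite-size susceptibilities, graph-topology
    descriptors (average shortest-path length, Louvain-maximized modularity)
    and geometric descriptors (radius of gyration, inertia-ellipsoid shape
    factor), then extracts finite-size scaling exponents by log-log
    regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
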