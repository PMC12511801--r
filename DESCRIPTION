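Package: surfconn
Title: Continuous Structural Connectivity on Cortical Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Kernel density estimation of continuous structural connectivity
    from tractography streamline endpoints on closed triangle meshes of the
    cortical surface. Builds Riemannian diffusion and Matern kernels from
    Laplace-Beltrami eigenpairs (cotangent finite elements with lumped mass),
    provides the spherical heat kernel as a baseline, and computes dense
    connectivity matrices by a fast matrix-product smoother that is exactly
    equivalent to the naive endpoint-pair estimator. Includes reliability
    (distance-based intraclass correlation) and identifiability metrics over
    repeated-scan collections, a two-bundle synthetic endpoint simulator with
    known ground truth, reduced-rank local group-difference testing on a
    locally supported basis, and a PCA plus ridge trait-prediction harness
    for bandwidth selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    glmnet,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
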