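Package: srmdrm
Title: Spatially Regularized Riemannian Classification of Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary motor-imagery EEG classification on the manifold of
    symmetric positive-definite (SPD) trial covariance matrices. Spatial
    filters learned by common spatial patterns (CSP) with a graph-Laplacian
    spatial-smoothness penalty built from electrode 3D coordinates reduce
    trial covariances to a low-dimensional SPD manifold, where Fisher
    geodesic discriminant filtering and minimum-distance-to-Riemannian-mean
    (MDRM) classification assign labels. Includes affine-invariant Riemannian
    geometry primitives, a synthetic two-class EEG generator with known
    ground truth, hyperparameter grid search by stratified cross-validation,
    CSP and plain-MDRM baselines, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
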