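Package: pocketvox
Title: Voxel Representation and 3D Convolutional Classification of
    Ligand-Binding Pockets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts ligand-binding pockets in protein structures into
    canonically oriented voxel tensors whose channels hold knowledge-based
    pairwise interaction energies, classifies the tensors with a compact 3D
    convolutional neural network, and explains classifications with
    class-activation maps aggregated to residue-level scores.  Includes a
    ligand-centered spherical grid builder with a three-step pocket
    refinement, SYBYL atom typing, distance-binned pair potentials,
    principal-axis canonical orientation, stratified and leave-one-group-out
    cross-validation, standard classification metrics, and a synthetic
    complex generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    rhdf5
Config/testthat/edition: 3
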