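Package: puvfcd
Title: Focal Cortical Dysplasia Detection by Positive Unanimous Voting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Voxelwise detection of focal cortical dysplasia (FCD) lesions in
    T1-weighted 3D brain volumes. Computes cortical feature maps (gray-matter
    thickness, intensity gradient, relative intensity, gray/white boundary
    width), differences them against a locally averaged normative model built
    from healthy controls, classifies voxels with four Gaussian discriminant
    classifiers (naive Bayes, linear, quadratic, and Mahalanobis discriminant
    analysis), and combines their labels by positive unanimous voting, so a
    voxel is called lesional only when all four classifiers agree. Connected
    regions smaller than a physical size threshold are relabelled as healthy
    after morphological opening, which turns the voxel map into a subject-level
    patient/control call. Includes a synthetic phantom generator with analytic
    partial-volume ground truth, a leave-one-out cross-validation harness, and
    voxel- and subject-level evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    pracma,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
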