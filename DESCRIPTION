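Package: tibiamech
Title: Subject-Specific QCT-Based Finite Element Analysis of the Proximal Tibia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds subject-specific finite element models of the knee from
    calibrated quantitative computed tomography (QCT) density volumes and
    derives regional mechanical metrics of the proximal tibia. Includes a
    parametric synthetic knee-phantom generator with in-image calibration
    rods and repeat-scan simulation, Hounsfield-to-density calibration,
    half-maximum-height bone segmentation, standing re-alignment from
    best-fit bone axes, voxel-based hexahedral and quadratic tetrahedral
    meshing with power-law density-to-modulus material mapping, a sparse
    linear elastostatic solver with body-weight load scaling, depth-banded
    regional stress/strain aggregation over seventeen anatomical regions,
    compartmental stiffness, and short-term precision (root-mean-square
    coefficient of variation) plus nonparametric group-comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
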