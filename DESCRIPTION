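Package: pulmo3d
Title: Lung Nodule Detection on CT with a 3D Feature Pyramid Detector and
    Location-History-Image False-Positive Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a pulmonary
    nodule detection pipeline for chest CT: reading and writing of CT
    volumes (MetaImage and NIfTI) with world/voxel coordinate handling,
    Hounsfield-unit windowing, isotropic resampling and classical lung
    masking, a self-supervised rotation-prediction pretext task for
    backbone pre-training, a 3D feature-pyramid convolutional detector
    with cube anchors and non-maximum suppression, Location History
    Images that summarise per-pixel intensity change across consecutive
    slices, a small convolutional classifier that removes false-positive
    candidates from the detector output, and FROC/CPM evaluation with
    size-stratified scoring.  A seeded synthetic CT phantom generator
    provides chest-like volumes with spherical nodules and tubular
    vessel distractors so that every stage runs end-to-end on a CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
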