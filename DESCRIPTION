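Package: mlnpipe
Title: Mediastinal Lymph Node Pseudolabel Fusion, Anatomical Filtering and
    Short-Axis Measurement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-segmentation computational pipeline for mediastinal lymph
    node analysis on chest CT label volumes: voxel-wise union fusion of
    ensemble prediction masks into pseudolabels, morphological postprocessing
    (3D connected components, hole filling, small-component removal),
    anatomy-constrained false-positive filtering against lung-derived regions
    of interest and 17 mediastinal structures, closed-form short-axis-length
    (SAL) caliper measurement on axial cross-sections with normal/enlarged
    classification, detection/segmentation/agreement evaluation metrics, the
    cyclical snapshot-ensemble learning-rate schedule, and a deterministic
    synthetic thorax phantom generator so that every stage is testable
    without CT data. Segmentation-model-agnostic: all inputs are label
    volumes in NIfTI format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
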