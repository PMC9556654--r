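Package: dcnet
Title: Voxel-Wise Degree Centrality Analysis of Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for voxel-wise binarized degree centrality
    (DC) analysis of resting-state BOLD fMRI. Provides a synthetic two-group
    cohort generator with planted hub-connectivity differences, BOLD
    preprocessing (volume discarding, motion quality control, nuisance
    regression, bandpass filtering, Gaussian smoothing), memory-bounded
    chunked computation of binarized degree-centrality maps, voxel-wise
    two-group inference with Gaussian random-field and permutation
    cluster-level correction, region-feature extraction with clinical
    correlation analysis, and RBF-kernel support-vector-machine
    classification with cross-validated sensitivity and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
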