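Package: vmadapt
Title: Multi-Context Visuomotor Adaptation MVPA Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for multi-context visuomotor
    adaptation fMRI experiments. Generates continuous-carryover task designs
    over three cursor transformations (-90 and +90 degree rotations and a
    horizontal mirror reversal), simulates erasing-task behavior and synthetic
    multi-voxel beta or BOLD data with a tunable context-representation
    commonality linked to performance, fits first-level GLMs, runs
    conjunctional cross-context searchlight decoding of visual, movement and
    task-context representations with a linear support vector machine, and
    performs group inference with threshold-free cluster enhancement and
    max-statistic permutation tests, including accuracy-performance
    correlation analyses with behavioral confounds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    RNifti
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
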