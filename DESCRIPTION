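Package: fmridecode
Title: Deep 3D Convolutional Decoding of Task States from 4D BOLD fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for decoding cognitive task states from 4D
    BOLD fMRI time series with a 3D residual convolutional network. Provides
    NIfTI/BIDS-events ingestion of block-design runs, extraction of labeled
    4D samples covering each task block plus the haemodynamic tail, a compact
    residual CNN with a 1x1x1 temporal front-end and a full-convolution head,
    temporal-crop augmentation, subject-wise cross-validation, transfer
    learning and learning-curve experiments, guided back-propagation pattern
    maps with group Cohen's d effect maps, and SVM-MVPA/GLM baselines
    (whole-brain, ROI and radius-3 searchlight). A built-in multi-subject
    block-design fMRI simulator with planted spatial activation footprints
    makes the whole pipeline testable without access to large public
    neuroimaging repositories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    e1071,
    generics,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
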