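Package: laminar
Title: Layer-Resolved Analysis of Laminar fMRI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for cortical-depth-resolved analysis of sub-millimetre
    (laminar) fMRI block designs: equi-volume depth surfaces and voxel-to-layer
    assignment, temporal filtering and condition GLMs, vasculature-bias
    correction (temporal-SNR and t-percentile voxel exclusion, layer voxel-count
    matching, within-layer z-scoring, spatial regression of middle-layer
    signals), layer-wise multivoxel decoding with leave-one-run-out
    cross-validation and permutation nulls, cross-validated linear discriminant
    contrasts with shrinkage noise covariance, informational connectivity from
    classifier hyperplane distances, and repeated-measures group statistics
    (Greenhouse-Geisser, Mauchly, Cousineau-Morey, Benjamini-Hochberg). A
    synthetic laminar-BOLD generator with full ground-truth bookkeeping supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
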