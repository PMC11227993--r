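Package: neurotime
Title: Intrinsic Neural Timescale Mapping and Mediation Analysis for
    Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates per-voxel intrinsic neural timescales (INT) from
    resting-state BOLD time series as the repetition-time-scaled area under
    the initial positive segment of the sample autocorrelation function,
    with temporal preprocessing (volume discard, confound regression,
    band-pass filtering, motion quality control), mask-aware Gaussian
    smoothing, network and spherical-ROI summarisation, group statistics
    (pooled-variance t tests with eta-squared, bootstrap Pearson
    correlations, Bonferroni correction, voxelwise GLM with
    permutation-based cluster-level family-wise error control), and a
    non-parametric bootstrap mediation suite linking regional grey-matter
    volume, local INT, network INT and cognitive scores. Includes a fully
    synthetic two-group AR(1) cohort generator with a planted mediation
    structure so every stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
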