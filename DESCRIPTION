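Package: brainpad
Title: Brain-Age Prediction and Brain-PAD Group Analysis from Structural Tissue Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Brain-predicted age difference (brain-PAD) analysis for
    voxel-based morphometry cohorts. Builds similarity (dot-product) kernels
    from concatenated grey- and white-matter tissue-probability maps, fits
    Gaussian-process age regression with 10-fold cross-validation and
    permutation significance testing, scores brain-PAD (predicted minus
    chronological age), and runs the downstream cohort statistics:
    pooled two-sample t-tests from raw data or printed summaries,
    Mann-Whitney U, chi-squared, Pearson correlation, covariate-adjusted
    group effects with interaction tests, BMI-matched subcohort filtering,
    and single-subject comparison against a normative cohort. Ships a
    synthetic-cohort generator (linear atrophy with subject-level aging
    variation and voxel noise) so the whole pipeline is testable without
    imaging data, plus packaged reference summary statistics for a
    Prader-Willi syndrome case-control study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
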