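Package: affrsa
Title: Representational Similarity Analysis of Affective Movie-Viewing fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses ROI-based representational similarity in
    a developmental movie-viewing design. Provides a synthetic study
    generator (stimulus schedules, voxel patterns with planted
    within-valence similarity, BOLD timeseries, motion traces, rater
    codings), ROI mask construction on a common MNI-like grid, motion
    quality control with boxplot-rule outlier detection, per-clip GLM beta
    estimation with nuisance regression and high-pass filtering,
    within-valence inter-movie Spearman similarity with Fisher Z
    transformation, and the group-level inferential layer: a two-stratum
    mixed ANOVA with effect sizes, Bonferroni-adjusted contrasts, an
    age-in-months multilevel model with intraclass correlation, and
    Krippendorff's alpha for rater agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    jsonlite,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
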