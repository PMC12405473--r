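Package: facegmm
Title: Landmark-Based Geometric Morphometrics for Facial Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end geometric-morphometrics pipeline for detecting
    condition-related facial-shape differences from noisy two-dimensional
    facial-landmark time series, as produced by automated landmark detectors
    running on video. Provides the landmark-scheme and CSV time-series data
    model, a quality-filtering cascade (detector confidence, head tilt and
    rotation outliers, minimum inter-sample interval, subject inclusion and
    per-subject top-k selection), generalised Procrustes superimposition,
    principal component analysis of shape with per-component two-group ANOVA
    under Benjamini-Hochberg false-discovery-rate control, subject-level
    paired effect size and post-hoc power, head-pose residualization by
    pooled within-group regression, two-group canonical variates analysis
    with Wilks' Lambda, and publication-style shape-difference figures.
    A seeded synthetic-data generator emulates the statistical structure of
    the target data (subject-specific base faces, condition displacement
    fields, similarity and head-pose nuisance, confidence scores) so the
    whole pipeline is testable without source videos.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
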