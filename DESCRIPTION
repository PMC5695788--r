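Package: voxelpower
Title: Power and Replication Simulation for Mass-Univariate Brain-Behavior Correlations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates statistical power, effect-size inflation, spatial
    extent, and replication overlap for mass-univariate voxel-wise
    brain-behavior correlation analyses. Constructs spatially smoothed
    per-voxel effect maps under two canonical scenarios (many weak diffuse
    correlations versus few strong localized ones), generates large
    synthetic cohorts with exactly-specified population correlations,
    repeatedly subsamples them, applies uncorrected or Benjamini-Hochberg
    FDR significance thresholds, and summarizes average power,
    at-least-one power, mean significant effect size, percent significant
    voxels, and Dice replication overlap across sample sizes. Also
    provides analytic power calculators for the Pearson correlation test
    (exact sampling-distribution integration and Fisher-z approximation),
    Fisher-z confidence intervals, and a type II/type I error-count
    balancing search for the uncorrected significance threshold.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
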