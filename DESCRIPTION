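Package: wmhnet
Title: Graph Analysis of Resting-State Functional Brain Networks Across
    White Matter Hyperintensity Severity
Version: 0.1.0
Authors@R:
    person("Maintainer", "wmhnet", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for graph-theoretical analysis of
    resting-state functional brain networks in cerebral small vessel
    disease cohorts graded by white matter hyperintensity (Fazekas)
    severity.  Covers seeded synthetic cohort generation with modular
    inter-regional covariance, temporal preprocessing of ROI time series
    (volume discarding, detrending, zero-phase Butterworth band-pass
    filtering, nuisance regression), Pearson/Fisher-z connectivity
    matrices, sparsity-thresholded binary and weighted networks,
    small-world and efficiency metrics with degree-preserving random
    nulls, and normality-gated two-group inference with FDR control,
    age adjustment and covariate-adjusted partial correlations with
    cognitive scores.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
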