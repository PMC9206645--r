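Package: mcnkit
Title: Maturational Covariance Network Analysis for Longitudinal Brain Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for constructing and comparing maturational covariance
    networks (MCNs) from two-timepoint regional gray-matter volumes.
    Converts longitudinal volumes into annualized fractional growth rates,
    removes covariate effects via externally studentized residuals, builds
    group-level inter-regional Pearson association matrices over a
    32-region atlas spanning the salience, default-mode and executive
    control networks, thresholds them at equal density, and tests group
    differences in within- and between-network coupling with label
    permutation and false-discovery-rate correction.  Includes a
    standardized early-life-stress scoring scheme for neonatal intensive
    care cohorts and a synthetic cohort generator with group-dependent
    block-correlation structure so that every stage of the pipeline can be
    validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    jsonlite
Config/testthat/edition: 3
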