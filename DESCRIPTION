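Package: mhrv
Title: Maternal Heart Rate Variability: Tachogram Cleaning, Breathing-Rate
    Estimation, and Mixed-Model Variance Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for maternal heart rate variability (mHRV)
    during pregnancy. Builds RR-interval tachograms from R-peak times and
    applies physiological-range, successive-difference, and neighbor
    artifact-rejection rules with a 25 percent recording-reliability gate;
    computes time-domain (SDNN, RMSSD) and sample-entropy HRV features;
    estimates median breathing rate from the uniformly resampled tachogram
    by empirical mode decomposition and Hilbert instantaneous frequency;
    and decomposes HRV variance into demographic, cardiorespiratory, and
    inter-subject components with multiple linear regression and
    random-intercept linear mixed models (intra-class correlation,
    boundary-corrected likelihood-ratio test, variance inflation factors,
    Cook's-distance diagnostics, and percentile effect curves). A
    synthetic-data module generates cohorts, feature-level repeated
    measures, and RR series with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
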