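Package: doceeg
Title: Resting-State EEG Biomarkers of Etiology and Outcome in Disorders of
    Consciousness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative EEG and functional-connectivity biomarkers from
    19-channel resting-state clinical EEG in patients with disorders of
    consciousness, and their use to screen for etiology/outcome markers and to
    classify six-month clinical outcome. Implements the full analysis chain:
    preprocessing (resampling, 1-30 Hz zero-phase bandpass, two-pass artefact
    rejection, 1 s re-epoching, linear detrending), quantitative EEG measures
    (z-scored band power, dominant frequency, permutation entropy, mean
    amplitude), surface-Laplacian referenced connectivity (weighted phase lag
    index on Morlet time-frequency data with per-subject surrogate
    thresholding, epoch-averaged magnitude coherence, histogram mutual
    information), region-of-interest summaries, mixed ANOVA/ANCOVA biomarker
    screening with Greenhouse-Geisser correction and bootstrap t-tests, and
    leave-one-subject-out diagonal-covariance linear discriminant
    classification with a logistic-regression control. A synthetic-cohort
    generator with controllable spectral peaks, lagged phase coupling, shared
    broadband sources and artefacts makes every stage testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
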