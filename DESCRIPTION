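Package: anespulse
Title: Temporal Pulse-Waveform Markers for Anesthesia Detection from
    Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting anesthesia versus
    non-anesthesia status from the shape of the photoplethysmogram (PPG)
    pulse.  Continuous pulse waveforms are cut into 5-second segments,
    screened for quality, smoothed with a Savitzky-Golay filter, freed of
    respiratory baseline wander, and delineated into individual beats by
    slope sign-change extrema detection.  Each beat is normalized in both
    time and amplitude, and thirteen temporal markers (rising time, total
    pulse area, and pulse widths at eleven fractional amplitudes) are
    extracted and averaged per 5-second segment.  Markers are screened by
    point-biserial correlation with the class label and Welch t-tests,
    and three classifiers (k-nearest neighbors with configurable
    Minkowski-family metrics and inverse-distance weighting, Gaussian
    discriminant analysis with a classification-cost decision rule, and a
    soft-margin support vector machine trained by sequential minimal
    optimization) are trained and evaluated with subject-grouped
    cross-validation, surrogate-model hyperparameter search, confusion
    metrics, and ROC/AUC.  A seeded synthetic PPG cohort generator
    emulates two-class cohorts that differ in pulse timing and width but
    not pulse area, with respiratory baseline wander, powerline noise,
    and motion artefacts, so the whole pipeline is testable without
    access to clinical waveform databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    e1071,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
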