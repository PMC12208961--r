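Package: cardiomatch
Title: Automated Template Matching for ECG-Free Heartbeat Detection in
    Cardiomechanical Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fully automated, ECG-free heartbeat detection in
    cardiomechanical signals (seismocardiography, gyrocardiography,
    forcecardiography) by normalized cross-correlation template matching.
    Provides zero-phase Butterworth and notch pre-processing,
    Savitzky-Golay respiration removal, automatic heartbeat-template
    selection with envelope-based reliability gating, NCC beat
    localization, inter-beat-interval extraction, a Pan-Tompkins R-peak
    reference detector, and the statistical evaluation layer
    (sensitivity/PPV, regression with confidence intervals, Bland-Altman
    agreement with a percentile fallback for non-normal differences).
    Includes a seedable synthetic generator of paired cardiomechanical and
    ECG records with ground-truth beat times, so the whole pipeline is
    testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
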