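Package: eegstate
Title: Real-Time Five-Parameter EEG Physiological State Indicator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline and calibration tools for a five-parameter
    EEG physiological state indicator (attention, fatigue, stress, and left
    and right hemispheric activity) intended for passive brain-computer
    interface monitoring. Provides readers and writers for multichannel EEG
    recordings (EDF/BDF/CSV) and event tables, 1-50 Hz bandpass filtering,
    artifact subspace reconstruction calibrated on a pre-task baseline,
    sliding-window power spectral density with baseline subtraction and
    band decomposition, a population-norm estimator that maps band powers
    onto a 0-10 scale, a target-detection paradigm scheduler with
    behavioral scoring, and a synthetic-EEG generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
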