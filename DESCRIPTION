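Package: pacsleep
Title: Phase-Amplitude Cross-Frequency Coupling Analysis of Sleep EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify phase-amplitude cross-frequency coupling (PACFC)
    in polysomnographic EEG and relate it to obstructive sleep apnea severity.
    Implements the Kullback-Leibler modulation index over phase-binned amplitude
    distributions, zero-phase Butterworth band decomposition with ICA-based
    artifact removal, rule-based apnea/hypopnea scoring from airflow and SpO2,
    SVM/SVR evaluation of stage classification and clinical-score prediction,
    scientific-control statistics (HRV, correlations, Bayesian two-group
    posteriors), and a synthetic polysomnography cohort generator that makes the
    whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    coda,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
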