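Package: hrvreact
Title: Heart Rate Variability Stress Reactivity in Fibromyalgia Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for time-domain heart rate
    variability (HRV) responses to an alternating relaxation / cognitive
    stress protocol, comparing fibromyalgia patients with healthy controls.
    Provides a synthetic cohort generator with known ground truth (phase
    dependent RR tachograms, ECG waveforms contaminated to surface-EMG
    recording conditions, covariates and questionnaire scores), ECG recovery
    from EMG-contaminated single-channel signals (detrending, powerline
    spectral flattening, Butterworth bandpass, time-delay-embedding PCA,
    QRS detection), time-domain HRV summarisation over protocol windows
    (HR, mean RR, RMSSD, SDNN), baseline-adjusted feasible generalized
    least squares reactivity models with group-by-time interactions, and
    constrained k-means stratification of patients by stress reactivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    nlme,
    mclust,
    optparse
Config/testthat/edition: 3
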