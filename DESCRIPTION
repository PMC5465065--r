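Package: zfeeg
Title: Multichannel Zebrafish EEG Simulation, Seizure Detection and
    Electrode Impedance Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for non-invasive multichannel electroencephalography
    (EEG) of adult zebrafish in acute chemoconvulsant (pentylenetetrazole)
    seizure experiments. Provides a ground-truth-labelled synthetic EEG
    generator (baseline activity, theta and spike-wave ictal discharges,
    sex-structured cohorts), EDF and CSV signal input/output with
    zero-phase band-pass filtering, threshold-based detection,
    segmentation and classification of epileptiform discharges including
    status-epilepticus flagging, Morlet continuous-wavelet time-frequency
    analysis, seizure onset-channel localization, equivalent-circuit
    modelling of the skin-electrode interface with a constant phase
    element, per-animal seizure metrics with two-sample comparisons, and
    a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
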