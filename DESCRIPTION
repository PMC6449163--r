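Package: dvca1
Title: Intrinsic Excitability, Resonance, and Dorsoventral Position Analysis
    for CA1 Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature extraction for current-clamp electrophysiology of
    hippocampal CA1 pyramidal neurons and the surrounding quantitative
    workflow of a dorsoventral excitability study: resting membrane
    potential, input resistance and rebound slope from step families;
    chirp (ZAP) impedance profiles and peak resonance frequency; action
    potential waveform and spike-train accommodation metrics with FI
    curves; sliding-window EEG seizure-candidate flagging; a printed
    linear regression mapping anatomical shape ratios to longitudinal
    slice position with zone classification; Sholl analysis, dendritic
    length and surface area on SWC morphologies; rectangular-ROI and
    20-bin radial immunostain profiling; Holm-Sidak multiple-comparison
    adjustment; and seeded synthetic-data generators (resonant
    integrate-and-fire neuron with closed-form impedance, spike
    templates, EEG with seizure epochs, random morphologies, layered
    images) providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    signal,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
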