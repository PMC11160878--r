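Package: seizr
Title: Semi-Automated Electrographic Seizure Detection with Interpretable Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed feature extraction and interpretable machine-learning
    classification of electrographic seizures in multichannel EEG/LFP
    recordings. Provides the full detection pipeline: reading EDF and HDF5
    recordings, antialiased downsampling, high-pass filtering and
    outlier repair, a per-window feature battery (line length, Hilbert
    envelope amplitude, band power, variance and relatives), redundancy
    pruning and univariate feature ranking, four classifier families
    (Gaussian naive Bayes, decision tree, stochastic-gradient linear
    models, passive-aggressive), balanced-accuracy grid-search tuning
    under stratified cross-validation, event-level post-processing and
    metrics (percent seizures detected, false detections per hour), and
    a synthetic seizure-signal generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    rpart,
    rhdf5,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
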