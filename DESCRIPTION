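Package: eegaffect
Title: EEG-Based Comparison of Emotional Responses to Photographs and Artwork
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, preprocessing and analysis pipeline for comparing
    EEG-derived emotional responses to photographs versus artwork. Generates
    synthetic 32-channel EEG sessions following a marker-coded playback
    protocol, preprocesses them into DEAP-format 60-second trials (128 Hz,
    4-45 Hz band), extracts 32x32 window samples, classifies valence and
    arousal with a multi-column recognizer fused by a probability-weighted
    vote, maps scores onto the nine Russell-model emotion keywords, and
    compares the two media groups with per-keyword two-sample t-tests,
    including simulation-based calibration of the test's size and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
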