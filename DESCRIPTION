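Package: hybridBCI
Title: Multi-Modal EEG Decoding for Brain-Controlled Flight
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Decoding stack for a hybrid brain-computer interface that steers
    a quadcopter with three EEG modalities: left/right-hand motor imagery
    decoded with complete-information common spatial patterns (CICSP) and a
    linear support vector machine, steady-state visual evoked potentials
    (SSVEP, 12.4 and 18 Hz) recognized by canonical correlation analysis
    against harmonic references, and conscious double eye-blinks detected by
    a trough-counting rule on the prefrontal channel. A mode-switching
    controller turns per-window decodings into a 1 Hz command stream, a
    synthetic-EEG generator provides calibrated test signals, and
    flight-performance metrics (Fitts-law analogous information transfer
    rate, gate acquisition time, boundary-crossing rate, percent task
    correct) summarize flight logs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'accessors.R'
    'io-text.R'
    'edf-io.R'
    'preprocess.R'
    'synth.R'
    'blink.R'
    'ssvep.R'
    'cicsp.R'
    'controller.R'
    'flight-metrics.R'
    'data-tables.R'
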