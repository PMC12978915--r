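Package: emgmap
Title: Multimuscle Surface EMG Strain Mapping for Procedural Protocols
Version: 0.1.0
Authors@R:
    person("EMG Map", "Developers", email = "emgmap@example.org",
           role = c("aut", "cre"))
Description: A pipeline for analysing multichannel surface electromyography
    (sEMG) recorded during a structured mammography positioning protocol.
    Sessions of 14 muscle channels are segmented into control and
    compression events, trimmed, bandpass filtered, and amplitude
    normalised against reference control recordings. Ten time- and
    frequency-domain metrics (RMS envelope statistics, waveform length,
    zero crossings, slope sign changes, Welch-spectrum mean and median
    frequency, spectral entropy, high-frequency power fraction, and
    spectral deformation) are extracted per channel and segment, compared
    across protocol stages with Bonferroni-corrected paired t tests, and
    summarised as a muscle-by-metric sensitivity matrix and a per-view
    percent-change activation map. A seeded synthetic-cohort simulator
    generates protocol-structured sEMG-like data so the whole pipeline is
    testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
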