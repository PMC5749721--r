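Package: flimpair
Title: Evaluation of Fluorescent Protein Pairs for FLIM-FRET Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking donor-acceptor fluorescent protein pairs
    for fluorescence lifetime imaging (FLIM) based Forster resonance energy
    transfer (FRET) experiments.  Predicts FRET performance from spectra
    (overlap integral, Forster radius, efficiency versus separation),
    models frequency-domain (homodyne phase/modulation) and time-domain
    (TCSPC) lifetime measurements, converts lifetimes to FRET efficiencies,
    scores assay potential with the Z'-factor statically and over time
    courses, and quantifies photobleaching drift and cross-platform
    concordance.  A synthetic-data generator emulates multi-day per-cell
    FLIM studies so every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
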