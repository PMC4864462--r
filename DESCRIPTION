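Package: translatomeSim
Title: Simulation of Polysome- and Ribosome-Profiling Bias and nanoCAGE 5' UTR
    Feature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how polysome-profiling and ribosome-profiling differ
    in sensitivity and bias when detecting MTOR-dependent shifts in translational
    efficiency. Provides a calibrated model of ribosome load versus sucrose-gradient
    sedimentation, a seeded simulator of per-gene ribosome-association shifts with
    both profiling readouts, population-level sweeps contrasting absolute and
    relative (globally centred) quantification for TOP, non-TOP and nonmover
    mRNAs, and a nanoCAGE-downstream pipeline: transcription start site peak
    calling from 5'-end tag counts, 5' UTR length estimation, 5' TOP motif and
    TISU element classification, reference-annotation comparison and exact
    enrichment testing. Includes generators for fully synthetic inputs with
    planted, machine-readable ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
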