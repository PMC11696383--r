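Package: protospike
Title: Spike-Train Analysis and Optical Character Recognition for
    Proteinoid Microsphere Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for electrical recordings of proteinoid
    (thermal protein) microspheres under optical stimulation with projected
    alphabet characters. Provides baseline removal, peak detection with
    topographic prominence, inter-spike-period and amplitude summary
    statistics, per-character response profiles, a threshold classifier with
    confusion-matrix metrics (with a reject option), Boolean-gate
    characterization of min-max normalized response tables, Gaussian-kernel
    density estimation with Scott's-rule bandwidth and Tukey box statistics
    for microsphere diameters, zero-phase Butterworth filtering and
    decibel power spectra, and a seeded synthetic-recording generator whose
    spike amplitude and period distributions are moment-matched to published
    per-character profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rlang,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    optparse,
    withr
Config/testthat/edition: 3
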