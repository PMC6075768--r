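Package: ramanstones
Title: Raman Chemical Imaging Analysis of Kidney Stones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Raman hyperspectral imaging of kidney
    stone sections. Simulates hyperspectral cubes of layered stone phantoms
    with known composition, preprocesses per-pixel spectra (Savitzky-Golay
    smoothing, asymmetric least squares baseline removal, low-signal
    porosity masking), resolves pure component spectra and concentration
    maps by multivariate curve resolution - alternating least squares
    (MCR-ALS) under non-negativity constraints, identifies components
    against a reference library of stone constituents, and derives
    structural readouts: abundance maps, minor-phase detection, layer
    thickness by radial ray casting, and discrimination of the two calcium
    oxalate monohydrate spectral variants by their main Raman peak.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    optparse,
    pracma,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
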