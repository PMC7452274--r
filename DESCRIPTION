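Package: quenchkin
Title: Kinetic and Spectral Analysis of Quenching in Light-Harvesting Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Global lifetime analysis of time-resolved spectroscopy of
    pigment-protein complexes. Provides IRF-convolved sequential
    compartmental kinetics, variable-projection global fitting of
    transient-absorption surfaces with multi-dataset lifetime linking and
    residual-bootstrap confidence intervals, multi-exponential TCSPC
    reconvolution fitting with amplitude- and intensity-weighted mean
    lifetimes, spectral quantifications (band ratios, difference spectra,
    vibronic gaps, singlet-singlet annihilation diagnostics), and a
    synthetic-data generator emulating quenched and unquenched LHCII
    trimers immobilized in gel or resuspended in buffer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
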