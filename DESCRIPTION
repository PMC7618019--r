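Package: drspectra
Title: Analytical Models of Diffuse Reflectance in Homogeneous Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward and inverse modelling of visible-range (450-650 nm)
    diffuse reflectance spectra of homogeneous, semi-infinite turbid media.
    Implements three analytical reflectance models (a hyperparameterised
    modified Beer-Lambert model, the Jacques 1999 path-length model, and the
    simplified Yudovsky 2009 semi-empirical model), a Monte Carlo photon
    transport reference simulator for slab geometry, chromophore-based
    optical property models for bulk tissue (hemoglobin) and gelatin
    phantoms (synthetic dyes plus intralipid scattering), hyperparameter
    calibration against reference spectra, bounded nonlinear least-squares
    parameter extraction (tissue oxygen saturation, blood volume fraction,
    Mie scattering parameters; dye fractions and intralipid concentration
    for phantoms), and an NRMSE/APE/correlation evaluation harness.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    lhs,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
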