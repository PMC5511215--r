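Package: mcfret
Title: Monte Carlo FRET Detection of Lipid Bilayer Nanodomains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward Monte Carlo simulation of time-resolved donor
    fluorescence decays in lipid bilayers containing circular nanodomains,
    the Baumann-Fayer analytical decay model for homogeneous bilayers, a
    chi-squared grid fitter that recovers nanodomain radius, area fraction
    and probe partition coefficients from donor decays, a nanodomain
    lipid-composition calculator, and z-scan fluorescence correlation
    spectroscopy diffusion analysis. Includes a synthetic-data generator
    emulating giant unilamellar vesicle experiments so the whole pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
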