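Package: optorep
Title: Simulation and Optical Entrainment Analysis of Light-Controllable
    Repressilators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic protein-only models of the repressilator and its
    optogenetic extension (the optorepressilator), in which a light-driven
    copy of one repressor makes the genetic clock resettable and entrainable
    by green-light pulses. Provides fixed-step simulation under arbitrary
    piecewise-constant light protocols, analytic digital-limit quantities,
    phase-response-curve computation, circle-map entrainment theory with
    fixed-point stability, heterogeneous-ensemble population signals and
    dephasing metrics, spectral frequency-ratio (Arnold tongue) analysis,
    and a synthetic-data generator emulating plate-reader and mother-machine
    fluorescence measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
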