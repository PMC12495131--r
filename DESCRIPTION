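Package: zeroflow
Title: Closed-Loop Cardiovascular Simulation and Analysis of Zero-Flow
    Blood Pressure After Cardiac Arrest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying zero-flow blood pressure and the mean
    circulatory filling pressure concept after cardiac arrest. Provides a
    closed-loop 21-compartment lumped-parameter (Windkessel) cardiovascular
    simulator with time-varying cardiac elastance, intrathoracic pressure
    coupling, and a discrete-time arterial-baroreflex and
    cardiopulmonary-reflex controller; scenario machinery for
    pentobarbital-like (reflex-inactive) and ventricular-fibrillation-like
    (reflex-active) arrest under euvolemia or 20 percent hypovolemia; a
    synthetic generator of pig-like hemodynamic recordings anchored to
    published group summary tables; and the processing chain used to compare
    model and experiment: zero-phase Butterworth low-pass filtering,
    fixed-time-point extraction, range-normalized RMSE, and repeated-measures
    group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
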