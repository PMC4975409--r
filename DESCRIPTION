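Package: atriafit
Title: Patient-Specific Fitting of a Minimal Atrial Ionic Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a four-variable minimal ionic model of the human atrial
    action potential in 1D cables and 2D sheets (explicit-Euler monodomain,
    no-flux boundaries), extracts action-potential morphology and APD/CV
    restitution with clinical-style S1-S2 and decremental pacing protocols,
    fits the model parameters to patient-style target curves by simulated
    annealing, and characterises the resulting two-dimensional spiral-wave
    dynamics (tip trajectories, rotation period, stability). Includes a
    synthetic-patient generator that emulates clinical monophasic action
    potential datasets for testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
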