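Package: stngpe
Title: Beta-Band Entrainment and Synchrony Analysis of a Subthalamo-Pallidal
    Network Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Conductance-based simulation of a reciprocally coupled
    subthalamic nucleus (STN) and external globus pallidus (GPe) network on a
    ring, driven by beta-band external input (pure sine, phase-jittered sine,
    or a phase-derived current built from a broadband cortical-surrogate
    signal).  Provides the full synchrony-analysis chain used to characterise
    Parkinsonian beta oscillations: surrogate local field potentials,
    zero-phase beta-band filtering, Hilbert-transform instantaneous phase,
    first-return maps of the spike/LFP phase difference with four-region
    partitioning and transition rates, and principal-component counting of
    network synchrony.  Amplitude-by-frequency sweep drivers map resonant
    entrainment (Arnold-tongue) structure and minimal-amplitude curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    signal,
    yaml,
    jsonlite,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
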