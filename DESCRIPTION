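Package: circentrain
Title: Two-Process Circadian and Sleep Model Simulation and Minimum-Time
    Light/Sleep Entrainment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates hybrid two-process models of human circadian rhythm
    and sleep regulation: the Jewett-Forger-Kronauer core body temperature
    oscillator (with second-order and phase-reduced variants) coupled to an
    exponential sleep homeostat through a hysteretic sleepiness automaton.
    Computes entrained 24-hour reference limit cycles and phase response
    curves, and solves minimum-time re-entrainment problems for light
    exposure (and optionally sleep/wake scheduling) using adjoint-based
    projected gradient descent with switching co-state jumps. Includes a
    nearest-neighbour feedback controller learned from optimal trajectories
    and scenario runners for jet-lag and night-shift recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
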