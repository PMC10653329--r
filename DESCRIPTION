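Package: phasing
Title: Dynamics of Intentional Desynchronization in Rhythmic Tapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying musical "phasing" -- intentional, controlled
    desynchronization from a metronome -- as a dynamical system. Implements a
    periodically forced phase oscillator with pulse-like coupling, frequency
    adaptation, and a context-gated intentional frequency bias; an analysis
    pipeline that converts finger-tap timestamps to wrapped and unwrapped
    relative phase, counts phasing laps, and classifies trials as successful,
    unsuccessful, incomplete (with subtypes), or noncompliant; parameter-space
    sweeps that map phasing outcomes over the intention parameters; and a
    synthetic-trial generator with known ground truth for validating the
    pipeline. Includes calibration of the pulse width so that the temporal
    basin of in-phase attraction is constant across metronome tempi.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
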