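Package: spindlefit
Title: Force-Based Encoding Models of Muscle Spindle Ia Firing Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing what muscle spindle Ia afferents encode during
    passive stretch. Provides pseudolinear candidate models of instantaneous
    firing rate built from whole-muscle force, dF/dt, and musculotendon or
    estimated fascicle length, velocity and acceleration; constrained
    least-squares fitting with a swept neuromechanical lag; randomized
    cross-validation with AICc and Akaike-weight model selection; classical
    spindle metrics (dynamic index, initial-burst analysis); and a synthetic
    data generator producing history-dependent muscle force (short-range
    stiffness, force relaxation, first-stretch enhancement) and ground-truth
    spike trains so every stage of the pipeline is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
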