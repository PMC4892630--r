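Package: proxyreg
Title: Noise Analysis of Proxy-Mediated Feedback and Incoherent
    Feedforward Gene Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to construct and analyse two-species gene-regulatory
    circuits in which an intermediary (proxy) species X regulates a species
    of interest Y, either by inhibiting production (feedback) or by
    mediating degradation (incoherent feedforward).  Provides normalized
    circuit construction with matched steady states and effective gains,
    deterministic adaptation and sensitivity analysis, exact stationary
    moments for ramp-inhibition feedback schemes, derivative-matching
    moment closure for the feedforward scheme, linear noise approximation
    with per-reaction variance decomposition, frequency-domain (H2)
    analysis of input-noise rejection, and ground-truth oracles based on
    finite state projection and exact stochastic simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
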