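Package: riposim
Title: Semi-Stochastic Simulation of Death-Receptor-Induced Caspase-8 Activation
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid stochastic-deterministic simulator of extrinsic apoptosis
    initiation in single cells. Random assembly of DISC/RIPoptosome platforms
    (RIP1 filaments, FADD, ProCaspase-8, cFLIP) is simulated with the direct
    Gillespie stochastic simulation algorithm, coupled by operator splitting to
    a deterministic effector-caspase feedback cascade (Caspase-3/-6/-8, XIAP)
    with a FRET-probe cleavage-rate death criterion. Includes receptor
    engagement at rapid equilibrium, receptor-cluster assignment, a full-SSA
    reference implementation, a mean-field deterministic model for parameter
    scans, and ensemble analytics for death-delay distributions, ramp noise and
    fractional killing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    mclust,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
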