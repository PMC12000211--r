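Package: gsracc
Title: Geometric Evidence Accumulation Models for Two-Alternative Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model discrimination for two-alternative forced-choice
    evidence accumulation. Implements a two-dimensional stochastic accumulation
    process in which the angle between the choice-option direction vectors is a
    free parameter, so that the diffusion decision model (opposed options) and
    independent racing accumulators (orthogonal options) arise as special cases.
    Provides trial-level simulation with projection stopping rules, model-specific
    start-point distributions and across-trial drift variability; accumulated
    evidence profiles with Sarle's bimodality coefficient and Kullback-Leibler
    based identification of the option angle; two-boundary Wiener first-passage
    densities; fixed-layout accuracy/response-time summary vectors; and amortized
    neural-network model classification and parameter estimation trained on
    simulated participants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    nnet,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
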