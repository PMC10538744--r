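Package: behenv
Title: Coupled Dynamics of Proenvironmental Behavior and a Perceived Environment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of a stochastic model in which agents
    switch between a baseline and an actively proenvironmental behavior under
    two pressures, social imitation and their own assessment of a perceived
    environmental state that in turn relaxes toward the population's mean
    impact. Provides exact simulation of the finite-population piecewise
    deterministic Markov process by thinning, integration of its
    large-population ordinary differential equation limit, equilibrium
    finding and regime classification (monostable, bistable, limit cycle),
    linear-noise (Ornstein-Uhlenbeck) fluctuation analysis with stationary
    covariances, and parameter-space sweeps of when the proenvironmental
    behavior is adopted consistently.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
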