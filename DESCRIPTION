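Package: gpcyeast
Title: Polynomial-Chaos Surrogates for Sensitivity Analysis and Bayesian
    Inference in Yeast Mating Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Legendre polynomial-chaos surrogate models for expensive
    simulators: total-degree basis enumeration, least-squares and
    l1-minimization (basis-pursuit denoising) coefficient recovery,
    k-fold cross-validation, analytic global derivative-based sensitivity
    coefficients, surrogate-accelerated Metropolis-Hastings MCMC and
    simulated annealing. Ships the two yeast pheromone-response models the
    method is demonstrated on: the heterotrimeric G-protein cycle ODE model
    and a mechanistic reaction-diffusion model of pheromone-induced Cdc42
    polarization on a circular membrane, together with synthetic-data
    generators so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
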