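Package: waterecmc
Title: Event-Chain Monte Carlo Simulation of Flexible SPC/Fw Water
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-reversible event-chain Monte Carlo (ECMC) sampling of the
    flexible SPC/Fw water model in a periodic cubic box. Implements the
    generalized Newtonian and straight ECMC variants as piecewise-deterministic
    Markov processes with exact factorized event rates, closed-form bond event
    times, Poisson thinning under bounding rates, cell-veto bundling of
    long-range Coulomb and Lennard-Jones factors through Walker alias tables
    and a Fibonacci-sphere discretization of velocity space, and a
    machine-precision Ewald summation for the molecular Coulomb factor. A
    reversible single-atom Metropolis sampler and polarization-autocorrelation
    analysis tools support cross-validation of the samplers.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils,
    yaml,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
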