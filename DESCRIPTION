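Package: aggkin
Title: Stochastic and Mean-Field Kinetics of Aggregation and Fragmentation in Finite Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling reversible cluster aggregation and fragmentation
    kinetics in systems with a small, fixed number of monomers, as encountered in
    molecular simulations of peptide self-assembly. Implements exact stochastic
    simulation of the aggregation-fragmentation master equation by the direct
    Gillespie method, numerical integration of the finite-size (modified)
    Smoluchowski rate equations obtained by mean-field moment closure, closed-form
    cluster-size distributions for the constant, additive and Blatz-Tobolsky
    kernels, an exact master-equation solver for small systems by full state-space
    enumeration, and a weighted least-squares workflow for fitting kernel
    parameters to averaged cluster-size time series with reduced chi-square model
    discrimination and Monte Carlo validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
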