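Package: hybridrd
Title: Hybrid Deterministic-Stochastic Simulation of Spatial
    Reaction-Diffusion Systems in Cell Biology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A general-purpose fixed-time-step simulator for spatial
    piecewise-deterministic Markov processes arising in cell biology:
    continuous concentration fields governed by reaction-diffusion
    partial differential equations with stochastic point sources,
    coupled to discrete particles undergoing field-dependent Markov
    state transitions and Brownian motion in the cell volume or on the
    cell membrane.  The continuous subsystem is integrated by a
    finite-volume semi-implicit scheme on rectangular grids and on
    triangulated closed surfaces; the discrete subsystem is advanced by
    acceptance-rejection sampling of exponential waiting probabilities,
    with particle densities binned into the finite-volume cells so that
    both subsystems share one spatial discretization.  The package
    ships independent reference solvers for validation (a closed-form
    expectation for separable channel models, a Gibson-Bruck
    next-reaction stochastic simulator, and direct Fokker-Planck
    solvers for well-mixed and spatially resolved single-channel
    problems, with Richardson extrapolation), together with ready-made
    models of calcium sparks, stochastically gated reversible binding,
    and spontaneous cell polarization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
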