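Package: scro
Title: Swarm-Based Chemical Reaction Optimization for Calibrating Dynamic
    Biological Models
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Parameter estimation for dynamic models of biochemical systems
    from noisy, incomplete time-series data, using the Swarm-based Chemical
    Reaction Optimization (S-CRO) hybrid metaheuristic together with three
    reference population methods (differential evolution, the firefly
    algorithm, and chemical reaction optimization).  Includes a registry of
    benchmark systems (a discrete nonlinear map, a two-switch transcriptional
    oscillator, and a DegS-DegU extracellular protease production network), a
    synthetic-data generator with percent white Gaussian noise and optional
    missingness, a chi-square residual-variance test of practical
    identifiability, and AIC-based model selection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
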