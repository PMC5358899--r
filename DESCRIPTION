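Package: runtumble
Title: Run-and-Tumble Gradient Navigation with Motion-Sensation Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Theory and simulation toolkit for run-and-tumble navigation of
    attractant gradients when the tumbling probability is coupled to motion
    through an adapting internal state. Provides the minimal chemotaxis model
    (logistic run probability, integral-feedback memory, rotational
    decorrelation), closed-form steady-state distributions of the internal
    state and the drift-speed identity, a spectral Fokker-Planck solver based
    on a Gegenbauer/Legendre angular-moment expansion, Euler-Maruyama Langevin
    engines in both (f, s) and (r, v) coordinates, an event-level agent
    simulator in physical units with receptor saturation and several gradient
    geometries, phase-plane analysis of the non-normal relaxation dynamics,
    and configuration-driven experiment runners that cross-validate all
    methods against each other.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    deSolve,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
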