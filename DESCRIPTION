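Package: plsneuro
Title: Polynomial, Piecewise-Linear and Step Function Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses neuron models whose right-hand sides are
    combinations of polynomial, piecewise-linear and step functions. Provides
    the three function families with their recursive definitions and
    continuity checks, a fully computed Wang-Buzsaki conductance-based
    reference model with fixed-step Euler simulation and F-I ramp protocols,
    four approximation routes (lookup table, polynomial fit, piecewise-linear
    fit, and a two-dimensional polynomial/piecewise-linear reduction built
    from the Rinzel gating-variable collapse), phenomenological integrator
    and resonator models with phase-plane and bifurcation analysis, and an
    NMDA-driven plateau-potential experiment with Poisson synaptic drive.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
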