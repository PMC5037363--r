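Package: chemofront
Title: Stochastic and Weakly Nonlinear Dynamics of Auto-Chemotactic Epithelial Fronts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuum free-boundary model of an epithelium advancing on a solid
    substrate under auto-chemotaxis, substrate friction (Darcy flow) and
    pressure-limited proliferation. Computes steady planar travelling fronts and
    the implicit front-velocity relation, solves the implicit dispersion relation
    for sinusoidal interface perturbations, locates the marginal double-zero
    (fingering) threshold and the selected wavenumber, classifies the
    chemotaxis-velocity phase diagram, integrates the Galilean-invariant
    interface-velocity equation and the coupled Turing-Hopf amplitude equations
    (pattern amplitude plus mean-velocity mode), and models biochemical noise
    below threshold: Ornstein-Uhlenbeck Langevin dynamics of interface Fourier
    modes, analytic and Monte-Carlo structure functions, multiplicative-noise
    sensitivities and the Novikov threshold shift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
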