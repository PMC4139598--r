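Package: lineagesde
Title: Stochastic Multistage Cell Lineage Models with Cytokine Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation toolkit for multistage stem-cell differentiation
    under cytokine feedback. Implements the deterministic n-compartment
    lineage model with quasi-steady-state feedback on self-renewal and
    proliferation, its Ito stochastic counterpart with multiplicative
    (environmental) noise integrated by the Euler-Maruyama scheme,
    exact geometric-Brownian-motion comparison processes that sandwich
    the stem-cell compartment pathwise, steady-state existence checks and
    solvers, and Monte-Carlo ensemble statistics (mean, quartiles,
    histograms, Lyapunov-exponent and extinction diagnostics) together
    with parameter presets, YAML configuration files and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
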