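Package: circdiss
Title: Information-Dissipation Trade-Offs in Binary Regulatory Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the trade-off between transmitted information
    and non-equilibrium dissipation in small stochastic regulatory circuits.
    Implements symmetric four-state Markov models of a two-component circuit
    with and without feedback, delayed mutual information between input and
    output, entropy-production functionals (instantaneous, steady-state, and
    time-averaged), constrained multistart optimization of information under
    dissipation budgets, a two-state bursty gene-promoter model with its
    dissipation decomposition and fast-switching limit, bipartite learning-rate
    diagnostics, and Gillespie-based Monte Carlo oracles for path entropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
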