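Package: operantfe
Title: Functional-Equation Models of Operant Learning via Picard Iteration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for a Volterra-type integral generalization of the
    classical two-operator learning equation of mathematical psychology.
    Provides exact symbolic Picard iteration with arbitrary-precision
    rational polynomial arithmetic, a grid-based numeric fixed-point solver
    for the integral and discrete forms, contraction (Lipschitz) certificates
    with Matkowski-type comparison functions and a-priori iteration bounds,
    and a stochastic simulator of the underlying two-choice and four-outcome
    operant Markov processes for Monte-Carlo cross-validation of fixation
    probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
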