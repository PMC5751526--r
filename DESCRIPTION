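Package: pbnctrl
Title: Finite-Horizon Optimal Control of Probabilistic Boolean Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models context-sensitive probabilistic Boolean networks with
    perturbation (CS-PBNp), the standard discrete stochastic model of small
    gene regulatory networks under external intervention.  Builds the exact
    control-dependent Markov decision process of a network, reduces the
    finite-horizon optimal control problem (minimal expected control plus
    terminal cost) to a minimum reachability-reward computation on a
    time-augmented MDP, solves it by backward induction with exact
    fixed-point decimal arithmetic available at small scale, extracts
    optimal intervention policies, supports hard upper bounds on the number
    of interventions, simulates policies by Monte Carlo, and generates
    probabilistic model-checker (PRISM) model and property code for
    external cross-validation, together with a bundled interpreter of the
    generated dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
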