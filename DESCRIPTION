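Package: qvoter2L
Title: Two-Level q-Voter Model with Independence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based Monte Carlo simulation and mean-field analysis of a
    q-voter model in which every agent carries both a public and a private
    binary opinion. Supports the two per-step updating orders (public level
    first, "act then think"; private level first, "think then act"), random
    sequential dynamics on complete graphs and arbitrary networks, rate
    equations for the two marginal concentrations and for the exact
    four-class (public, private) joint description, stationary states with
    stability analysis, critical points and order-disorder transition-type
    classification, dissonance and public-private opinion correlation, and a
    classifier for the sixteen response patterns of the four-dimensional
    (Willis-scheme) taxonomy of social response.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
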