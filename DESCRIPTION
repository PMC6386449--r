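Package: taexcite
Title: Excitable Dynamics of Toxin-Antitoxin Modules with mRNA Cleavage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic modeling of type II toxin-antitoxin
    (TA) modules such as mazEF, in which an endoribonuclease toxin cleaves the
    module's own transcript above a threshold level. Provides the dimensional
    four-variable ODE model, its nondimensionalized form, the two-dimensional
    quasi-steady-state reduction and extensions (secondary TAT complex,
    transcriptional autoregulation by operator binding, growth-rate and
    translational inhibition); phase-plane tools (nullclines, fixed points,
    regime classification); continuation of equilibria with Hopf detection and
    limit-cycle metrics; an exact Gillespie stochastic simulator for every
    model variant; and utilities for detecting and timing toxin excitations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
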