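Package: channelpop
Title: Population-of-Models Analysis of Ion-Channel Diversity in
    Conductance-Based Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how ion-channel diversity shapes the density,
    stability and connectedness of valid regions in the conductance parameter
    space of neuron models. Provides a compact surrogate family of
    conductance-based granule-cell models (5-, 9- and 15-channel rosters) with
    a fixed-step current-clamp simulator, extraction of nine spike features and
    a multi-objective fitness expressed in units of experimental standard
    deviation, a derivative-free conjugate-direction search with step
    escalation and randomized restarts, population sampling and random-walk
    stability protocols, hyperplane connectivity analyses, and a probabilistic
    toy model (independent, Gaussian-copula, distributed and
    nonlinear-interaction sampling) with exact Irwin-Hall oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
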