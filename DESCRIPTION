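Package: memfermi
Title: Spatial Prisoner's Dilemma with Memory-Damped Fermi Updating
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo simulator for the weak prisoner's dilemma on a
    periodic square lattice in which the Fermi imitation rule is damped by
    the stability of each agent's own recent strategy history. Agents record
    their strategies over the previous M rounds; the run length n of the
    most recent entries that match the current strategy scales the
    probability of imitating a randomly chosen neighbour by the memory
    factor H = 1 - (1 - beta) * n / M. Provides lattice construction and
    payoff accumulation over von Neumann neighbourhoods, per-agent memory
    buffers with a configurable reset policy, asynchronous and synchronous
    Monte Carlo schedulers (compiled core), observables (cooperation rate,
    mean strategy stability, cooperator and defector retention
    probabilities), a config-driven experiment runner with parameter sweeps
    and figure recipes, plain-text lattice snapshot input/output, and PNG
    rendering of strategy patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
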