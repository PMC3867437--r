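Package: coopbreed
Title: Evolutionary Dynamics of Cooperative Breeding Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form lifetime-fitness accounting and evolutionary dynamics
    for a game-theoretic model of cooperative infant care in a hominin-like
    life history. Three female reproductive strategies (Independent,
    Opportunistic, and Cooperative Mothers) and two male strategies
    (Coalition and Non-coalition Males) interact through kin-selection
    assortment, assortative pair formation, paternity certainty, and
    extra-pair mating. The package provides replicator dynamics on the
    female strategy simplex, basin-of-attraction estimation via the unstable
    Cooperative-Opportunistic edge equilibrium, Monte Carlo parameter sweeps
    over empirically motivated ranges, and a stochastic individual-lifetime
    simulator that serves as a brute-force validation oracle for every
    closed-form fitness expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    graphics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
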