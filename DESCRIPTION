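Package: commonpool
Title: Mechanism Design for Iterated Common-Pool Resource Trust Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and mechanism-design toolkit for an iterated
    multiplayer trust game played over a regenerating common-pool resource.
    Provides the game engine (pool dynamics with growth factor and carrying
    cap), hand-coded allocation mechanisms (equal/proportional/mixed weighted
    family, a random Dirichlet baseline, and a pool-conditioned interpolating
    baseline with exponent calibration), scripted player archetypes and a
    fixture-log generator, behavioural cloning of players with recurrent
    categorical-uniform policies, a permutation-equivariant graph-network
    allocation mechanism trained by gradient ascent on cumulative player
    surplus, and the full descriptive analysis suite (surplus, Gini,
    inclusivity, depletion, exclusion events, lagged offer regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    patchwork,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
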