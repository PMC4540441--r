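Package: reefbn
Title: Expert-Elicited Spatial Bayesian Networks for Coral Reef Decline Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and applying expert-elicited discrete Bayesian
    networks to map the ten-year probability of hard-coral-cover decline across
    individual reefs under climate-change and local-management scenarios.
    Includes aggregation of 4-point expert elicitations into mean, pessimistic
    and optimistic parameterizations, interpolation of full conditional
    probability tables from elicited endpoint distributions, exact inference by
    variable elimination, discretization of continuous environmental layers
    into three-category evidence states, proportional downscaling of coarse
    fishing-effort grids, no-take zoning rules, scenario state-shifting,
    per-reef prediction, zone comparisons, relative-change maps, and a fully
    seeded synthetic-data generator for reef fleets and expert pools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
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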