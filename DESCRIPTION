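Package: coevosim
Title: Deterministic Simulation of Human-Plant Mutualism and Coevolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the coupled dynamics of a human and a plant
    population linked by mutualism. Each population grows under a
    discrete-time Verhulst-Pearl logistic map whose carrying capacity is
    raised by the other population, while the distribution of each
    population across mutualism types evolves by replicator dynamics with
    deterministic undirected variation. Provides end-state classification
    (no coevolution, full coevolution, partial stationary, oscillatory),
    run-level output statistics (coevolution and dependency coefficients,
    timing of type shifts), grid and Latin-hypercube parameter sweeps,
    tipping-point location by bisection, and random-forest ranking of
    parameter importance. Trajectories and sweep results are returned as
    tidy tibbles; fitted runs support tidy(), glance() and autoplot().
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    randomForest,
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
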