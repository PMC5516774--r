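Package: cartox
Title: Oxidative-Stress Dynamics of Blunt-Impacted Articular Cartilage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Kinetic model of chondrocyte mitochondrial dysfunction after an
    injurious blunt impact to articular cartilage. Tracks live cells with
    functional and dysfunctional mitochondria together with relative reactive
    oxygen species (ROS), ATP and glycosaminoglycan (GAG) levels as a
    five-variable ODE system with homeostasis-preserving parameter
    constraints. Provides stiff integration of the system, RMSE calibration
    of the parameters and of the post-impact ROS burst against longitudinal
    viability/ATP/GAG observations via a seeded particle-swarm optimizer,
    forward local sensitivity analysis for all parameters and initial
    conditions, numerical equilibrium and linear stability analysis, and a
    synthetic-observation generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    optparse,
    purrr,
    readr,
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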