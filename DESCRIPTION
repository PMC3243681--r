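Package: glioswitch
Title: Glucose-Driven miR-451/AMPK Switch and Glioma Growth-Invasion Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the mutual-antagonism network between miR-451 and the
    CAB39/LKB1/AMPK complex that switches glioblastoma cells between
    proliferative and migratory phenotypes in response to glucose, and the
    coupled one-dimensional reaction-diffusion-taxis model of tumor growth
    and invasion it drives. Provides equilibrium continuation with
    saddle-node (fold) detection and hysteresis analysis for the switch,
    a finite-volume operator-splitting solver for the full six-field
    spatial system (tumor cells, extracellular matrix, matrix
    metalloproteinases, glucose, miR-451, AMPK) with pulsed glucose
    injection schedules, and metrics for growth-invasion cycle counting
    and parameter sweeps. Results are returned as tibbles with tidy() and
    glance() methods and ggplot2-based autoplot() visualisations.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
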