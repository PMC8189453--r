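Package: dlgradient
Title: Reaction-Diffusion Modelling of the Dorsal/NF-kB Nuclear Gradient
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates nuclear Dorsal (NF-kB) gradient formation along the
    dorsal-ventral axis of the early Drosophila embryo with a mass-action
    reaction-diffusion network coupling Dorsal, its IkB inhibitor Cactus and
    the Toll receptor. Provides steady-state integration of the compartmental
    model, wild-type and mutant genotype scenarios, decomposition of nuclear
    Dorsal into Toll-dependent and direct-flow entry routes, gradient shape
    metrics, genetic-algorithm calibration of the dimensionless parameters
    against quantified gradient profiles, recovery of dimensional time and
    diffusion scales, and a synthetic-data generator emulating embryo
    quantifications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    graphics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
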