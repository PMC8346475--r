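Package: potflow
Title: Unified Potential-Flow Models of Swimming, Flying, and Diving Animals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic two-dimensional potential-flow model of a thin plate
    moving normal to itself, and the locomotion quantities it implies for
    animals: the complex potential, velocity field, edge circulation and
    unsteady pressure jump of the plate; closed-form added masses for flat
    plates, prolate spheroids and elliptical discs; water-entry impact force
    and pressure of diving bodies with the associated allometric scaling
    exponents; thrust, lift balance, swim-speed scalings, Reynolds and
    Strouhal numbers for flapping fliers and swimmers. Includes a synthetic
    comparative-animal population generator and log-log fitting utilities so
    every scaling result can be exercised on seeded data, plus a small
    command-line interface.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
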