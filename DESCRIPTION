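Package: curvlamina
Title: Curvature-Driven Nuclear Lamina Dilution and Rupture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how Gaussian curvature of the nuclear
    envelope drives local dilution of the lamin-B and lamin-A meshworks and
    nuclear envelope rupture. Implements a two-state Boltzmann model of
    semiflexible lamin filament detachment from a curved membrane, sigmoidal
    response fitting, osculating-circle curvature estimation on nuclear
    contours, intensity-based dilution metrics for micropipette aspiration
    and spindle-shaped nuclei, cohort-level rupture statistics (multi-site
    independence, curvature-regime enrichment, critical strain-rate hinge
    fits), and seeded synthetic-data generators that emulate every input
    class so the full pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    rlang,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
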