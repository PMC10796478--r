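Package: grazekit
Title: Growth, Clearance and Ingestion Rates for Microzooplankton Grazing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing batch-culture predator-prey grazing
    experiments between a ciliate grazer and a microalgal prey. Computes
    prolate-ellipsoid cell biovolumes from length/width measurements,
    exponential and log-linear growth rates from cell-count time series,
    and Heinbokel-style clearance and ingestion rates from paired
    grazed/monoculture flasks, with automatic detection of the linear
    prey-decline window. Includes seeded permutation tests for treatment
    effects on prey trajectories, a high/low read-abundance co-occurrence
    screen for amplicon survey data, and a closed-form predator-prey
    simulator used for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
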