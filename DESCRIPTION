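Package: swidcarbon
Title: Carbon Stocks and REDD+ Scenarios in Shifting-Cultivation Landscapes
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates plot-level aboveground carbon from forest-inventory
    records using ensembles of allometric equations (trees, lianas, standing
    and fallen deadwood, leaf litter), fits log10-linear carbon-recovery
    models over fallow age as linear mixed models with AICc multimodel
    inference and Nakagawa R-squared, and runs a 30-parcel Monte Carlo
    landscape simulator comparing business-as-usual and forest-sparing
    (REDD+) management scenarios. A calibrated synthetic-data generator
    emulates the sampling design of a shifting-cultivation chronosequence so
    the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    ape,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
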