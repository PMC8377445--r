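Package: thermodev
Title: Temperature Scaling of Developmental Timing via Arrhenius Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing how developmental rates scale with
    temperature. Converts staged event-timing tables from time-lapse
    recordings of embryos into per-embryo interval durations and rates,
    fits linear and quadratic models in Arrhenius coordinates to estimate
    apparent activation energies with confidence intervals, compares
    interval slopes by ANCOVA with post-hoc power, selects between linear
    and quadratic temperature dependence by BIC, and models composite
    rates of sequential multi-reaction networks, including random network
    simulation and constrained worst-case curvature maximisation. A
    synthetic-data generator produces timing tables and enzyme absorbance
    traces with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
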