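Package: khscm
Title: Step-Down Costing of Health Facilities and Essential-Package Episodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A facility-level step-down costing engine for national health
    sector cost analysis, modelled on the Kenya Health Sector Costing Model.
    Provides annualization of capital and staff costs (straight-line
    depreciation, inflation averaging, currency conversion, staff
    minute-costing), sequential step-down allocation of support cost centres
    to final cost centres, unit costs per outpatient visit, admission and
    bed-day, costing of essential-health-package (KEPH) condition episodes
    with demand-side adjustment from patient exit interviews, national
    aggregation into stratum-by-category cost matrices, and what-if scenario
    simulation (standard bed occupancy, coverage response under a
    fixed/variable cost split). Includes a seeded synthetic-data generator
    that emulates a stratified facility sample and can be calibrated to a
    target national cost matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
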