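Package: grasscut
Title: Dynamic Cutting and Manuring Management for Simulated Pre-Alpine Grassland
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained daily/hourly simulator of managed temperate
    grassland productivity. Couples a four-compartment plant growth model
    (growing-degree-day phenology, dynamic carbon allocation, light- and
    CO2-saturating photosynthesis scaled by drought, temperature and nitrogen
    limitation of rubisco activity, Q10 respiration, senescence) to a layered
    tipping-bucket soil water balance with snow and a minimal mineral-nitrogen
    pool. Cutting and slurry-application events are scheduled on the fly from
    the simulated biomass by a rule engine with target-biomass thresholds and
    day-of-year fallbacks, alongside static calendars and a nitrogen-capped
    policy. Includes a stochastic daily weather generator, delta-change climate
    scenarios with transient CO2 pathways, model evaluation statistics and
    first-cut shift-per-degree analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
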