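Package: fluxphen
Title: Carbon-Flux Phenology, Trends and Driver Attribution from Daily NEE
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for long-term analysis of daily net ecosystem CO2 exchange
    (NEE) from eddy-covariance towers: aggregation of half-hourly fluxes to
    daily carbon sums with joint uncertainty, extraction of the net carbon
    uptake period (start and end of season) from smoothed daily NEE,
    Mann-Kendall/Theil-Sen trend detection at annual, seasonal, per-percentile
    and per-day-of-year resolution, Pettitt change-point detection, and
    attribution of daily NEE to meteorological drivers via gradient-boosted
    trees with exact SHAP values, including driver-shift statistics around
    phenological transitions. A seasonally realistic synthetic generator for
    daily meteorology and NEE provides ground truth for every stage.
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
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
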