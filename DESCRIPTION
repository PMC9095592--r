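Package: mhwtrends
Title: Marine Heatwave Detection and Nonparametric Trend Analysis for Coastal Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects marine heatwaves in daily sea-surface temperature series
    against a fixed-baseline day-of-year climatology (seasonally varying mean
    and 90th-percentile threshold), computes per-event and per-period metrics
    (heatwave days, event counts, mean, maximum and cumulative intensity),
    aggregates them by year, season and biogeographical realm, and runs a
    nonparametric trend suite per stratum: Mann-Kendall test, Theil-Sen slope,
    Pettitt change-point test and before/after trend re-fitting, classifying
    each stratum as increasing, decreasing or unchanged. Includes a synthetic
    daily-SST generator (seasonal cycle, piecewise-linear warming, AR(1)
    noise, injectable warm events) so every stage can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
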