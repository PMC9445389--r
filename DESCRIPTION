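Package: broileract
Title: Early Locomotor Activity Descriptors and Growth Analysis for
    RFID-Tracked Broilers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify early-life locomotor activity of broiler
    chickens tracked with a grid of floor RFID antennas and to relate it to
    growth. Parses second-resolution registration logs, applies group-level
    missing-data and light-period rules, converts antenna registrations to
    daily average distances moved, and computes five per-bird dynamic
    activity descriptors (mean distance, skewness, trend-residual RMSE,
    lag-1 autocorrelation of deviations, and daily sample entropy of binned
    activity classes). Computes average daily gain from weekly weights and
    links descriptors to growth with tie-corrected Kendall rank
    correlations (bootstrap confidence intervals), Wilcoxon rank-sum
    quartile comparisons, and a sum-to-zero linear model with backward
    stepwise selection. Includes a pen-scale movement and growth simulator
    with known ground truth so the full pipeline is testable without farm
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
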