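Package: tidalcarbon
Title: Blue-Carbon Accumulation Accounting for Tidal Wetlands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives site-level soil carbon accumulation rates (CAR) from
    sediment-core measurements (loss-on-ignition conversions, a self-packing
    bulk-density mixing model, top-30-cm averaging), estimates relative
    sea-level rise (RSLR) trends from annual tide-gauge series with a
    30-to-60-year bridging regression, upscales CAR to a wetland polygon
    inventory by radius-based interpolation with explicit standard-error
    propagation, reproduces the associated statistical surface (one-way
    ANOVA with Tukey HSD letters, Pearson and partial correlations, a
    CAR~RSLR linear model with cluster-robust or mixed-model fits), and
    projects national tidal-wetland carbon sequestration to 2100 under RCP
    scenarios with a critical-RSLR cap and Monte-Carlo uncertainty bands.
    Includes a calibrated synthetic-data generator so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    jsonlite,
    lme4,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
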