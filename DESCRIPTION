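Package: pamscape
Title: Soundscape Metrics, Detection Ranges and Acoustic Occurrence for
    Passive Acoustic Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for long-term passive acoustic monitoring (PAM) of
    cetaceans from moored hydrophone recordings: count-to-pressure
    calibration and duty-cycle data inventories, Welch-style 1-minute
    averaged power spectral density and band sound pressure levels,
    long-term spectral averages, a simple band-energy event detector,
    sonar-equation detection-range estimation by Monte Carlo over source
    level and calling-depth distributions with pluggable propagation-loss
    models, sunrise/sunset (NOAA solar calculator) light/dark
    classification with diel and seasonal occurrence summaries, and 8-day
    environmental compositing (sea surface temperature, chlorophyll-a)
    with Kruskal-Wallis and Dunn post-hoc site comparisons. Includes
    seeded simulators for shaped ambient noise, injected call templates,
    occupancy event series and environmental series so the full pipeline
    can be exercised end to end with known ground truth.
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
    lubridate,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
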