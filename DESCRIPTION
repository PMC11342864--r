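Package: gametel
Title: Gaming Telemetry Sessionization, Behavioral Metrics and Emotion Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening-oriented analysis of competitive-gaming
    telemetry. Partitions match histories into gaming sessions with an
    inter-match gap rule, computes historical and recent behavioral metric
    suites (monthly, weekly, day-part and weekday breakdowns, rolling
    week-over-week percent differences), and summarizes per-second facial
    emotion streams (rolling-median smoothing, event-aligned medians around
    kills and deaths, per-match and first/last five-minute averages). A
    seeded synthetic-data generator produces match histories, event logs and
    emotion streams with known ground truth for validation, and chart-data
    builders plus ggplot2 methods export clinician-oriented report figures.
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
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
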