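Package: inboxstress
Title: EHR Inbox Work Patterns and Wearable-Sensed Physician Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links physicians' electronic health record (EHR) inbox work,
    reconstructed from timestamped access-log events, to physiologic stress
    measured as heart-rate-variability (HRV) based stress scores from a
    wrist-worn device. Provides audit-log sessionization with an idle
    cutoff, hourly time attribution by activity and message type, temporal
    classification of inbox work relative to scheduled clinic hours,
    block detection and a daily inbox-batching indicator, validity-filtered
    hourly and daily stress-duration summaries, Gaussian-mixture clustering
    of physician work-pattern profiles with group comparisons, and a
    Poisson mixed-effects association model of work-hours stress minutes
    with valid HRV minutes as an exposure offset. A seeded synthetic-cohort
    generator emulates rosters, schedules, log-event streams and stress
    series with configurable group prototypes so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    lme4,
    mclust,
    cluster,
    car,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    readr
Config/testthat/edition: 3
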