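Package: orbreaks
Title: Feasibility of Operating-Room Break Relief from Surgical Time Prediction Bounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates whether an anesthesiologist supervising one, two, or
    three cyclically adjacent operating rooms can give a 15- or 30-minute
    break to the practitioner in a room, using per-procedure 5% lower
    prediction bounds of surgical time fitted on the log scale with the
    Student t distribution from historical case records. Classifies each
    future case under configurable break policies (break duration, 15-minute
    lead-in, clock window for the break start), aggregates feasibility
    percentages with exact 99% Clopper-Pearson intervals, runs
    Sidak-corrected service-by-weekday stratum analyses, and ships a seeded
    synthetic-schedule generator emulating three facility archetypes so the
    whole pipeline is testable without institutional data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
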