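Package: fieldsync
Title: Offline-First Data Collection and Synchronisation for Long-Term
    Individual-Based Field Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline-first toolkit for long-term individual-based field
    studies of social animals: a versioned entity-attribute-value store kept as
    a single SQLite file per device, a two-way replica/hub synchronisation
    protocol with per-entry acknowledgements and last-writer-wins conflict
    resolution, a domain layer for behavioural field protocols (group
    composition visits with GPS tracks, weighings, reproductive status records,
    20-minute focal follows with per-minute neighbour scans, group events),
    typed CSV export for analysis, and a seeded synthetic field-season
    generator so every component is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
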