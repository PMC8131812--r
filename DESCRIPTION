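Package: abascan
Title: Detection and Cohort Analysis of Autumn Breeding Attempts in
    Colony-Attendance Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing automated-gateway (PIT-tag weighbridge)
    crossing records from seabird colonies. Cleans raw crossing logs
    (registered-individual, direction, body-mass and 40-minute
    pseudo-replication filters), aggregates them into daily attendance and
    nest-occupancy series, detects the autumn breeding attempt (ABA) window
    each year with a threshold rule anchored on the March post-molt minimum,
    segments the window into courtship peaks and the prelaying-exodus trough,
    classifies spring/summer breeders by autumn attendance, and compares the
    two cohorts' ages and sex ratios across years with paired t-tests. A
    seeded individual-based simulator generates realistic crossing logs,
    individual registers and nest-check records with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
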