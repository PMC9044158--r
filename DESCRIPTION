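Package: nof1diary
Title: N-of-1 Trigger Screening and Phase Comparison for Daily Binary Symptom Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for semiautomated single-subject (N-of-1) analysis of daily
    binary symptom and trigger diaries. Screens candidate lifestyle factors
    against outcomes with the phi coefficient at lag 0 and lag 1, compares
    outcome recurrence between baseline and intervention phases with exact
    tests of proportions, simulates diaries to estimate power and type-I
    error for single-subject designs, and reproduces feasibility-survey
    summary statistics from packaged fixtures. Includes a command-line
    interface for the analyze/compare/simulate/power/survey workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
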