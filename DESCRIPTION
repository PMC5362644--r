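Package: querytiming
Title: Within-Song Timing Analysis of Audio Identification Query Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analyzing when, within a song, audio identification
    queries (e.g. Shazam-style lookups) are initiated. Reads and cleans
    per-song query-offset logs, tests offset distributions for departure from
    uniformity with perturbed Kolmogorov-Smirnov tests, detects migration of
    query mass toward song beginnings over a hit song's life cycle via a
    chi-squared proportion-test sweep, profiles histogram slopes time-locked
    to salient musical events (song start, vocal onset, chorus onset) against
    a random-window baseline, and quantifies how many queries are needed for
    a stable offset distribution using total variation distance between
    disjoint subsamples. Includes a seeded synthetic query-log generator so
    the full pipeline is testable without large proprietary datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
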