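Package: screenrhythms
Title: Weekly Activity Rhythms, NMF Chronotype Components, and Sleep
    Inference from Smartphone Screen Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies daily and weekly rhythms of phone use from
    timestamped screen-on/off event logs. Builds normalized 168-bin
    hour-of-week activity profiles per participant, decomposes the
    population matrix with a from-scratch hierarchical alternating least
    squares (HALS) non-negative matrix factorization under the squared
    Frobenius objective with multi-restart selection, chooses the number
    of components by the consensus-clustering cophenetic correlation
    coefficient, infers nightly sleep, wake and mid-sleep times from the
    longest hourly inactivity run in noon-anchored 24-hour windows, and
    correlates component weights with the inferred sleep variables.
    Includes a synthetic event-log generator with planted diurnal
    archetypes, weights and sleep windows so every stage has a recovery
    test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
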