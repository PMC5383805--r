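Package: querypulse
Title: Event-Window Analysis of Search-Query Surveillance Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for infodemiology studies of web-search behaviour around
    major societal events. Classifies raw search queries against a keyword
    taxonomy, resolves clicked URLs to registrable domains with top-level
    domain, content and advocacy classifications, and contrasts before/after
    event windows through cross-tabulations (counts, percentage change,
    cumulative shares) against an event-agnostic control topic. Includes a
    seeded synthetic search-log generator with a step-plus-decay event
    effect and pre-event spikes, daily trend series with robust spike
    detection and return-to-baseline estimation, and a pipeline runner that
    writes all tables plus a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
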