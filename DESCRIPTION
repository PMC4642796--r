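Package: clicklog
Title: Mining Clinical Search Logs for Engagement and Drug-Safety Alert Uptake
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing usage logs of online clinical information
    resources. Reads sessionized search/topic-view event logs, annotates
    free-text queries against a synonym lexicon, expands seed terms into
    curated term sets, computes topic-view dwell times and classifies short
    versus long clicks with a geometric-mean boundary, summarises engagement
    per topic and per search term with Hampel-identifier thresholds, mines
    frequent contiguous topic-view sequences with their initiating search
    terms, and detects drug-safety-alert uptake as sustained deviations of
    term-matched daily query volume from baseline, compared against an
    online-media mention stream. Includes a seeded synthetic-data generator
    that emulates the statistical structure of such logs (log-normal dwell
    mixtures, seasonal query volume, a delayed sustained alert response)
    with planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
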