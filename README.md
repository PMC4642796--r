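# clicklog

Mining the usage logs of online clinical information resources — the
search-and-read clickstreams of health care professionals — for
information-seeking behaviour and drug-safety-alert uptake.

When clinicians look something up in an evidence resource, the log records a
free-text query, the topic pages viewed afterwards, and timestamps, all tied
together by a session identifier. Those traces support three kinds of
analysis that this package implements as a tested pipeline:

1. **What is searched.** Queries are annotated against a synonym lexicon
   (greedy longest match at token boundaries, each term mapped to one or
   more concepts carrying a semantic category: diseases and symptoms,
   drugs, devices, procedures). Seed terms expand into curated term sets by
   a one-hop closure through the lexicon (seed → concept → all synonyms),
   with an explicit exclusion list standing in for manual review. Matched
   volumes aggregate by month, body system, and category, and join against
   disease-burden tables.

2. **How results are read.** The dwell time of a topic view is the time to
   the next event that terminates it (a new search, or a view of a
   different topic; a session's final view has no terminator and is
   dropped). Views are split into *short clicks* and *long clicks* at the
   geometric-mean boundary

   > b = exp( (1/n) Σᵢ ln dᵢ )

   i.e. the mean of log dwell times mapped back to seconds. Engagement is
   summarised per topic and per initiating search term; robust high/low
   thresholds on long-click proportions come from the Hampel identifier,
   median ± k·1.4826·MAD (k = 3), and groups are compared with the
   Mann-Whitney U test. Frequent contiguous topic-view sequences (lengths
   2-4) are mined with their initiating search terms.

3. **How behaviour changes after a safety alert.** Daily term-matched query
   counts (and media-document counts from a news stream) are smoothed with
   a trailing 7-day moving average; a sustained signal is a run of at least
   `min_run` = 3 days above baseline mean + 3 SD. The package reports onset
   lag versus the alert date, elevated duration, the lag between the
   professional-log response and the media spike, and pre/post-alert
   changes in initiating-term vocabulary, dwell times, and
   adverse-event-specific search counts.

Because real resource logs are proprietary, the package ships a seeded
synthetic-data generator (`gen_lexicon()`, `gen_logs()`, `gen_media()`)
that emulates their statistical structure — log-normal dwell mixtures
attached to terms, seasonal query volume, a delayed sustained alert
response against an immediate short-lived media spike — and records the
realized ground truth alongside, so every stage is testable end to end.

## Worked example

```r
library(clicklog)

cfg   <- generator_config(seed = 20, span = as.Date(c("2011-06-01", "2011-12-31")),
                          sessions_per_day = 60)
logs  <- gen_logs(cfg)           # synthetic usage log + lexicon + ground truth
media <- gen_media(cfg)          # matching media-document stream

## engagement
dw <- dwell_table(logs$events)
(b <- fit_boundary(dw$duration))
#> <click boundary: 159.26 s (fit on 23559 durations)>
dw <- label_dwells(dw, b)
hampel_bounds(topic_engagement(dw)$long_click_proportion, clamp = c(0, 1))
#> <Hampel bounds: low 0, high 1 (median 0.4702, scaled MAD 0.1983)>

## alert uptake: log vs media
alert_set <- term_set("celexa", c("celexa", "citalopram"))
dc  <- daily_query_counts(logs$events, alert_set, logs$lex, span = cfg$span)
sig <- detect_signal(dc$matched, baseline = c(cfg$span[1], cfg$alert$date - 7))
sig
#> <signal: onset 2011-09-03, peak 2011-09-15, elevated 60 days (threshold 7.346)>
md   <- daily_media_counts(media$docs, alert_set, logs$lex, span = cfg$span)
msig <- detect_signal(md, baseline = c(cfg$span[1], cfg$alert$date - 7))
msig
#> <signal: onset 2011-08-24, peak 2011-08-24, elevated 6 days (threshold 11.32)>
compare_streams(sig, msig)
#> $onset_lag_days  [1] 10
#> $duration_ratio  [1] 10

## pre/post alert report
pre_post_report(logs$events, cfg$alert$date, alert_set,
                term_set("spec", c("long qt", "heart", "rhythm")),
                logs$lex, boundary = b)
#> <alert report: alert 2011-08-24>
#>   unique initiating terms: 3 pre -> 6 post
#>   mean dwell on drug topics: 2358.4 s pre -> 1969.9 s post
#>   drug+specificity searches: 2 pre -> 431 post
```

Reading the output: the click boundary lands where the short/long dwell
mixture balances; the media stream spikes on the alert day and subsides
within a week, while professional queries rise 10 days later and stay
elevated for two months; and after the alert the drug is searched with a
broader vocabulary, more often together with the adverse-event terms, and
its pages are read for less time per visit.

A thin command-line wrapper over the same functions is installed at
`inst/cli/clicklog.R` (subcommands `validate`, `annotate`, `termset`,
`engagement`, `sequences`, `surveil`, `simulate`).

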