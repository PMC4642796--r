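---
title: "Dwell-time engagement and alert-uptake surveillance in clinical search logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dwell-time engagement and alert-uptake surveillance in clinical search logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clicklog)
```

## The data model

A usage log of an online clinical information resource is a table of
timestamped events, each carrying a session identifier, an institution
label, an action type and a payload. Three actions occur: a free-text
`search` (payload: the query string), a `topic_view` (payload: the
identifier of the topic page opened), and a `subtopic_view` (payload:
`parent_topic/suffix`, a click within a topic page). Sessions are taken as
given by the session identifier — the package deliberately does not infer
session boundaries or detect user switching, which would require external
models and cannot be validated from the log alone. Within a session,
events are ordered by timestamp with ties broken by file order; logs have
seconds resolution, so ties are common and an unstable order would make
dwell computation nondeterministic. One timezone applies per file and
defines the calendar dates used by all daily aggregation.

## Query annotation and term sets

Free-text queries are matched against a lexicon mapping normalized terms to
concepts (synonymy, many-to-many), concepts to a semantic category
(diseases and symptoms, drugs, devices, procedures, or none), and concepts
to one another through an acyclic parent-child hierarchy. Normalization is
deliberately simple and fully specified so that it is testable: Unicode
NFKC, lower-casing, punctuation to spaces, whitespace collapsed. No
spelling correction, inflection handling or word-sense disambiguation is
attempted; a misspelled query simply fails to match, which is itself
informative (such queries surface among the terms that never produce long
clicks).

Matching is greedy, longest-match-first, left to right, aligned to token
boundaries, and non-overlapping, so a query containing both
"diabetes insipidus" and "diabetes" as lexicon terms yields the longer
match only. Industrial annotators make many policy choices; this one is
the simplest that is deterministic and order-independent, and the test
suite pins it against a brute-force maximal-match oracle.

Term sets — the unit of counting for body systems, condition groups and
drugs — are built by a one-hop expansion: each seed term is looked up, and
the complete synonym sets of the concepts it maps to are unioned with the
seeds. Deeper transitive closure through the hierarchy is available behind
an option but off by default: every extra hop compounds over-broadening,
and the curation this mirrors was a review that *removed* terms. That
review is mechanized as an explicit exclusion list stored with the set, so
a curated set is reproducible from its definition file.

## Dwell times and the click boundary

The dwell time of a topic view is the difference between its timestamp and
the timestamp of the next event that terminates it: a new search, or a
view of a *different* topic. Subtopic clicks inherit their parent topic
and so extend the current dwell rather than ending it; consecutive views
of the same topic merge into one block for the same reason. A session's
final block has no terminator — its dwell is unobservable — and is
dropped. Zero-length blocks (possible at seconds resolution) are dropped
too, because the log transform that follows is undefined at zero; they
carry no usable duration signal either way.

The short/long classification boundary is the mean of the log-transformed
durations mapped back to seconds — the geometric mean. The base of the
logarithm cancels and is irrelevant. Durations strictly above the boundary
are long clicks; a duration exactly at the boundary counts as short (the
defining rule uses "less than" for short and "above" for long, so equality
must be assigned by convention; short is the conservative choice for a
quantity read as evidence of engagement). Each dwell is attributed to the
nearest preceding search anywhere earlier in the session, not only an
immediately adjacent one, since intervening topic views do not change
which query led the user into the reading chain.

Per-topic and per-term long-click proportions are exact ratios of integer
counts. High/low regimes on those proportions come from the Hampel
identifier, median ± k·1.4826·MAD, with k = 3 — the conventional
three-sigma-equivalent multiplier; the scale constant makes the MAD a
consistent estimator of a Gaussian standard deviation. Bounds on
proportions are clamped to [0, 1], and an all-identical input collapses
the bounds and is flagged degenerate rather than erroring. Group contrasts
(e.g., unique initiating-term counts for high- versus low-engagement
topics) use the Mann-Whitney U test: exact enumeration when both groups
have at most eight observations and no ties, otherwise the tie-corrected
normal approximation with continuity correction.

## Topic-view sequences

Within a session, maximal stretches of views uninterrupted by a search
form runs; subtopic views map to their parent and immediately repeated
topics are collapsed, since subtopic clicks within one page would
otherwise manufacture spurious repeat patterns. Every contiguous window of
length 2-4 of every run is counted once per occurrence (sliding window) —
fixed-size patterns are reported out of longer browsing streams, so
counting only maximal runs would miss most of them. The search immediately
preceding a run is credited to each of its windows; runs that open a
session contribute to counts but not to term tallies. Beyond length 4,
sequences are dominated by back-and-forth alternation between two topics
("switching", quantified by `switching_fraction()` as the share of
positions `i` with `topicᵢ = topicᵢ₊₂`), which is navigation noise, hence
`max_len = 4` by default. Ranking ties break lexicographically on the
topic tuple so output is deterministic.

## Alert-uptake surveillance

Daily series of term-matched and total search counts (and of media
documents mentioning the terms — counted at the document level, once per
document, versus event-level counting for queries) are gap-filled with
zeros and smoothed with a *trailing* 7-day moving average; the first six
days are undefined. A trailing window is causal — usable day by day in a
live surveillance setting — whereas a centred window needs the future.

"A deviation from the mean" is not executable as written, so the signal
rule is parameterized explicitly: threshold = baseline mean + k·SD with
k = 3, onset at the first day opening `min_run` = 3 consecutive days above
threshold, elevation ending at the first day opening `min_run` consecutive
days at or below it, and the peak at the maximum after onset. The run
requirement suppresses single-day Poisson excursions; on null series the
false-onset rate is bounded at the 5% level in the acceptance suite. The
baseline defaults to the whole series but should exclude a window around a
known event date (the tests and the acceptance script exclude from one
week before the alert), because at desk-scale series lengths the planted
response would otherwise inflate the baseline itself. A degenerate
baseline (SD = 0) falls back to mean + 1 count and is flagged.

The pre/post alert report splits the log at the alert date (or into
configurable symmetric windows) and, over the topics reached from
drug-term searches, reports unique initiating-term counts and long-click
proportions per window, mean dwell seconds, and the count of searches
containing a drug term together with at least one alert-vocabulary term —
the "specificity" of post-alert searching.

## The synthetic-data generator

Real resource logs and news corpora of this kind are proprietary, so the
generator emulates the statistical structure the analysis assumes, with a
single seed driving every draw and the realized ground truth recorded in a
sidecar object (tests never re-derive planted values from the emitted
log).

* **Volume.** Sessions per day are Poisson (default 150/day over a
  two-year span — a deliberate desk-scale stand-in for logs that are
  orders of magnitude larger). Each session is one search followed by 1-6
  views; about half the sessions close with a follow-up search, which
  terminates the last view, while the rest end on a view whose dwell is
  naturally unobservable.
* **Dwell.** A two-class log-normal mixture attached to search terms:
  short-class terms draw gaps around 30 s, long-class around 600 s, both
  with σ = 0.8 on the log scale. Attaching the class to the *term* is the
  point — it reproduces the strongly bimodal per-term long-click
  proportions that motivate the term-level engagement summary, and puts
  the overall geometric mean near the hundred-odd-second boundary typical
  of such resources. σ = 0.8 keeps the classes separable but overlapping
  (≈3% of draws cross the boundary).
* **Seasonality.** A designated flu-like term set carries a sinusoidal
  annual modulation (amplitude 0.6, peak January).
* **Alert.** From alert date + 10 days, for 60 days, the designated drug's
  search rate is multiplied by 5; its query vocabulary broadens by a
  factor of 3 (adding adverse-event and dosing modifiers); and post-alert
  dwell means shift down by 0.12 on the log scale — a delayed, sustained,
  vocabulary-broadening response. Drug-search sessions stay on the drug's
  topic pages (a drug-information lookup, not exploratory browsing), which
  keeps the initiating-term vocabulary of those pages interpretable.
* **Media.** A Poisson baseline of matching documents (5/day) plus an
  additive spike at the alert date decaying geometrically to 5% over 10
  days — an immediate, short-lived response, in contrast to the log.
* **Structure.** One boosted disease→drug topic transition plants a
  dominant view sequence; remaining transitions and random browsing supply
  background. Categories are allocated 70/20/5/5 across diseases, drugs,
  devices and procedures, matching the dominance of disease searches in
  such resources.

What the generator does *not* emulate: natural-language query text (terms
are drawn verbatim from the lexicon, so annotation recall is perfect by
construction), typos, institution-level concentration, user switching
inside sessions, and any correlation between media coverage and query
content beyond the shared alert date. Passing tests therefore demonstrate
that the pipeline's operations are correct and that planted effects of
realistic shape and size are recovered — not that annotation would recall
free text well, nor that the signal rule is powerful against every real
confounder.

## Problem sizes and numerical choices

The test suite runs oracle-equivalence checks on 100 seeded random logs of
a few hundred events each; planted-recovery checks use one two-year
default-configuration log (engagement bimodality), twenty two-year logs
(alert onset and duration), and one hundred one-year null logs with the
alert effect disabled (false-onset rate) — sizes chosen so the full suite
completes in minutes on one CPU while keeping binomial error well inside
the asserted margins. Module-level recovery tests use smaller spans and
rates; the pre/post recovery test plants a stronger dwell shift (−0.3)
than the default, a clearly detectable effect at its sample size.

Remaining conventions, collected: ties at the click boundary are short;
ties in pattern ranking are lexicographic; dwell blocks with zero duration
are dropped; days with zero total queries yield fraction 0; the moving
average emits NA for its warm-up days; and all randomness in generation
flows from one integer seed per generator function.
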