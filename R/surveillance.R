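#' Construct a daily series
#'
#' A date-indexed vector of non-negative values with no gaps (one row per
#' calendar day).
#'
#' @param dates Consecutive `Date`s (or the first date, with `values`
#'   supplying the length).
#' @param values Numeric values, one per day (`NA` allowed to mark
#'   undefined smoothed values).
#' @param label Optional label for the series.
#' @return A tibble of class `daily_series` with columns `date`, `value`.
#' @export
daily_series <- function(dates, values, label = NULL) {
  if (length(dates) == 1 && length(values) > 1) {
    dates <- seq(as.Date(dates), by = "day", length.out = length(values))
  }
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(values), length(values) >= 1)
  if (length(dates) > 1 && any(diff(dates) != 1)) stop("daily series must have no date gaps")
  if (any(values < 0, na.rm = TRUE)) stop("daily series values must be non-negative")
  out <- tibble::tibble(date = dates, value = as.numeric(values))
  class(out) <- c("daily_series", class(out))
  attr(out, "label") <- label
  out
}

as_daily_from_dates <- function(event_dates, span, label = NULL) {
  days <- seq(span[1], span[2], by = "day")
  counts <- table(factor(as.character(event_dates), levels = as.character(days)))
  daily_series(days, as.integer(counts), label)
}

#' Daily term-matched and total query counts
#'
#' Per calendar day (in the log's timezone): the number of search events
#' whose annotation matches the term set, and the number of all search
#' events. Both series share the same gap-filled date span.
#'
#' @param events A `log_events` tibble.
#' @param set A [term_set()].
#' @param lex A [lexicon()].
#' @param span Optional `c(start, end)` dates; defaults to the span of the
#'   search events.
#' @return A list with `matched` and `total` [daily_series()].
#' @export
daily_query_counts <- function(events, set, lex, span = NULL) {
  searches <- events[events$action == "search", ]
  if (nrow(searches) == 0) stop("log contains no search events")
  tz <- attr(searches$timestamp, "tzone") %||% "UTC"
  dts <- as.Date(searches$timestamp, tz = tz)
  if (is.null(span)) span <- range(dts)
  span <- as.Date(span)
  matched <- match_events(events, set, lex)
  list(
    matched = as_daily_from_dates(as.Date(matched$timestamp, tz = tz), span,
                                  label = paste0("queries: ", set$name)),
    total = as_daily_from_dates(dts, span, label = "queries: total")
  )
}

#' Read a media-document stream
#'
#' JSON-lines (one object per line with fields `title`, `timestamp`, `url`,
#' `content`) or TSV with the same columns and a `#`-prefixed header.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"tsv"`; guessed from the extension by default.
#' @param tz Timezone for timestamps.
#' @return A tibble with columns `title`, `timestamp` (POSIXct), `url`,
#'   `content`.
#' @export
read_media <- function(path, format = NULL, tz = "UTC") {
  if (is.null(format)) {
    format <- if (grepl("\\.jsonl$|\\.ndjson$", path)) "jsonl" else "tsv"
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (format == "jsonl") {
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    rows <- lapply(lines, jsonlite::fromJSON)
    df <- tibble::tibble(
      title = vapply(rows, `[[`, "", "title"),
      timestamp = as.POSIXct(vapply(rows, `[[`, "", "timestamp"),
                             format = "%Y-%m-%dT%H:%M:%S", tz = tz),
      url = vapply(rows, `[[`, "", "url"),
      content = vapply(rows, `[[`, "", "content")
    )
  } else {
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    mat <- do.call(rbind, parts)
    df <- tibble::tibble(
      title = mat[, 1],
      timestamp = as.POSIXct(mat[, 2], format = "%Y-%m-%dT%H:%M:%S", tz = tz),
      url = mat[, 3], content = mat[, 4]
    )
  }
  if (any(is.na(df$timestamp))) stop("unparseable media timestamp(s)")
  if (any(!nzchar(paste0(df$title, df$content)))) stop("media document with empty title and content")
  df
}

#' Write a media-document stream as JSON lines
#'
#' @param docs A media tibble (see [read_media()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_media <- function(docs, path) {
  lines <- vapply(seq_len(nrow(docs)), function(i) {
    jsonlite::toJSON(list(title = docs$title[i],
                          timestamp = format(docs$timestamp[i], "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                          url = docs$url[i], content = docs$content[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Daily counts of media documents mentioning a term set
#'
#' A document counts (once, regardless of how many mentions it contains) on
#' its publication day if the annotation of its normalized title plus
#' content contains at least one term of the set.
#'
#' @param docs A media tibble (see [read_media()]).
#' @param set A [term_set()].
#' @param lex A [lexicon()].
#' @param span Optional `c(start, end)` dates; defaults to the document span.
#' @return A [daily_series()].
#' @export
daily_media_counts <- function(docs, set, lex, span = NULL) {
  tz <- attr(docs$timestamp, "tzone") %||% "UTC"
  dts <- as.Date(docs$timestamp, tz = tz)
  if (is.null(span)) span <- if (nrow(docs)) range(dts) else stop("no media documents")
  span <- as.Date(span)
  hit <- query_matches(paste(docs$title, docs$content), set, lex)
  as_daily_from_dates(dts[hit], span, label = paste0("media: ", set$name))
}

assert_aligned <- function(a, b) {
  if (nrow(a) != nrow(b) || any(a$date != b$date)) {
    stop("daily series are not date-aligned")
  }
}

#' Fraction of daily queries matching a term set
#'
#' Elementwise `matched / total`; days with zero total queries yield 0 by
#' convention.
#'
#' @param matched,total Date-aligned [daily_series()].
#' @return A [daily_series()] of fractions.
#' @export
fraction_series <- function(matched, total) {
  assert_aligned(matched, total)
  v <- ifelse(total$value == 0, 0, matched$value / total$value)
  daily_series(matched$date, v, label = attr(matched, "label"))
}

#' Trailing moving average of a daily series
#'
#' Mean over the trailing `window` days (causal, suitable for
#' surveillance); the first `window - 1` days are `NA`.
#'
#' @param series A [daily_series()].
#' @param window Window length in days (default 7).
#' @return A [daily_series()].
#' @export
moving_average <- function(series, window = 7) {
  stopifnot(window >= 1)
  if (window > nrow(series)) stop("window longer than the series")
  v <- as.numeric(stats::filter(series$value, rep(1 / window, window), sides = 1))
  daily_series(series$date, pmax(v, 0), label = attr(series, "label"))
}

#' Scale a daily series by a constant
#'
#' Used to overlay series of different magnitudes on one axis.
#'
#' @param series A [daily_series()].
#' @param factor Positive multiplier.
#' @return A [daily_series()].
#' @export
scale_series <- function(series, factor) {
  stopifnot(factor > 0)
  daily_series(series$date, series$value * factor, label = attr(series, "label"))
}

#' Detect a sustained signal in a daily series
#'
#' The threshold is the baseline mean plus `k` baseline standard
#' deviations. Onset is the first day opening at least `min_run`
#' consecutive days above threshold; the elevated period ends on the first
#' day opening `min_run` consecutive days at or below threshold; the peak
#' is the day of the maximum value from onset onward. Pass a smoothed
#' series to detect on the smoothed scale. `NA` values (e.g., the head of
#' a moving average) never count as above threshold and are excluded from
#' the baseline.
#'
#' @param series A [daily_series()].
#' @param baseline Optional `c(start, end)` dates delimiting the baseline
#'   period; default is the whole series. Exclude a window around a known
#'   event to avoid contaminating the baseline.
#' @param k Threshold multiplier (default 3).
#' @param min_run Consecutive days required above (and later below)
#'   threshold (default 3).
#' @return A list of class `signal` with `onset_date` (NA if never
#'   triggered), `peak_date`, `elevated_duration_days`, `threshold`,
#'   `baseline_mean`, `baseline_sd`, `degenerate`.
#' @export
detect_signal <- function(series, baseline = NULL, k = 3, min_run = 3) {
  v <- series$value
  d <- series$date
  in_base <- if (is.null(baseline)) rep(TRUE, length(v)) else
    d >= as.Date(baseline[1]) & d <= as.Date(baseline[2])
  base <- v[in_base & !is.na(v)]
  if (length(base) < 2) stop("baseline period too short")
  mu <- mean(base)
  sdv <- stats::sd(base)
  degenerate <- sdv == 0
  threshold <- if (degenerate) mu + 1 else mu + k * sdv
  above <- !is.na(v) & v > threshold
  run_above <- run_start_of_length(above, min_run)
  if (is.na(run_above)) {
    return(structure(list(onset_date = as.Date(NA), peak_date = as.Date(NA),
                          elevated_duration_days = 0, threshold = threshold,
                          baseline_mean = mu, baseline_sd = sdv,
                          degenerate = degenerate),
                     class = "signal"))
  }
  onset <- run_above
  below <- !above
  below[seq_len(onset)] <- FALSE
  end_run <- run_start_of_length(below, min_run)
  duration <- if (is.na(end_run)) length(v) - onset + 1L else end_run - onset
  post <- v
  post[seq_len(onset - 1)] <- NA
  peak <- which.max(post)
  structure(list(onset_date = d[onset], peak_date = d[peak],
                 elevated_duration_days = as.integer(duration),
                 threshold = threshold, baseline_mean = mu, baseline_sd = sdv,
                 degenerate = degenerate),
            class = "signal")
}

# index of the first position opening a run of `len` consecutive TRUEs
run_start_of_length <- function(x, len) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  i <- which(r$values & r$lengths >= len)
  if (length(i) == 0) return(NA_integer_)
  ends[i[1]] - r$lengths[i[1]] + 1L
}

#' @export
print.signal <- function(x, ...) {
  if (is.na(x$onset_date)) {
    cat("<signal: none (threshold", format(x$threshold, digits = 4), ")>\n")
  } else {
    cat(sprintf("<signal: onset %s, peak %s, elevated %d days (threshold %.4g)>\n",
                format(x$onset_date), format(x$peak_date),
                x$elevated_duration_days, x$threshold))
  }
  invisible(x)
}

#' Compare a log signal with a media signal
#'
#' Onset lag (log minus media, in days) and the ratio of elevated
#' durations; errors if either stream never triggered.
#'
#' @param log_signal,media_signal [detect_signal()] results.
#' @return A list with `onset_lag_days` and `duration_ratio`.
#' @export
compare_streams <- function(log_signal, media_signal) {
  if (is.na(log_signal$onset_date)) stop("no onset detected in the log stream")
  if (is.na(media_signal$onset_date)) stop("no onset detected in the media stream")
  list(
    onset_lag_days = as.integer(log_signal$onset_date - media_signal$onset_date),
    duration_ratio = log_signal$elevated_duration_days /
      media_signal$elevated_duration_days
  )
}

#' Pre/post alert engagement and specificity report
#'
#' Splits the log at the alert date (or into symmetric windows of
#' `window_days` around it) and reports, for every topic reached from a
#' drug-term-matched search: unique initiating-term counts and long-click
#' proportions before vs after; plus mean dwell seconds on those topics,
#' and the count of searches containing a drug term together with at least
#' one specificity term (e.g., the adverse event vocabulary of the alert),
#' before vs after.
#'
#' @param events A `log_events` tibble.
#' @param alert_date The alert `Date`; must fall within the log span.
#' @param drug_set [term_set()] for the drug of interest.
#' @param specificity_set [term_set()] of alert-related terms.
#' @param lex A [lexicon()].
#' @param boundary Optional [fit_boundary()] result or seconds; fit on all
#'   dwells when NULL.
#' @param window_days Optional symmetric window length (days) before and
#'   after the alert; default uses the whole log split at the alert date.
#' @return A list of class `alert_report`: `alert_date`, `topics` (a
#'   tibble), `pre_mean_dwell`, `post_mean_dwell`, `specificity_pre`,
#'   `specificity_post`, `boundary_seconds`, window bounds.
#' @export
pre_post_report <- function(events, alert_date, drug_set, specificity_set, lex,
                            boundary = NULL, window_days = NULL) {
  searches <- events[events$action == "search", ]
  if (nrow(searches) == 0) stop("log contains no search events")
  tz <- attr(events$timestamp, "tzone") %||% "UTC"
  alert_date <- as.Date(alert_date)
  span <- range(as.Date(events$timestamp, tz = tz))
  if (alert_date <= span[1] || alert_date > span[2]) {
    stop("alert date outside the log span")
  }
  alert_ts <- as.POSIXct(paste(alert_date, "00:00:00"), tz = tz)
  if (is.null(window_days)) {
    lo <- min(events$timestamp); hi <- max(events$timestamp)
  } else {
    lo <- alert_ts - window_days * 86400; hi <- alert_ts + window_days * 86400
  }
  in_pre <- function(ts) ts >= lo & ts < alert_ts
  in_post <- function(ts) ts >= alert_ts & ts <= hi

  drug_searches <- match_events(events, drug_set, lex)
  if (!any(in_pre(drug_searches$timestamp)) || !any(in_post(drug_searches$timestamp))) {
    stop("no drug-matched search events in the pre or post window")
  }

  dwells <- dwell_table(events)
  if (is.null(boundary)) boundary <- fit_boundary(dwells$duration)
  dwells <- label_dwells(dwells, boundary)

  # topics reached from drug-term searches
  drug_initiated <- query_matches(
    ifelse(is.na(dwells$initiating_term), "", dwells$initiating_term),
    drug_set, lex)
  drug_topics <- unique(dwells$topic_id[drug_initiated])
  dw <- dwells[dwells$topic_id %in% drug_topics, ]
  dw$window <- dplyr::case_when(in_pre(dw$start) ~ "pre",
                                in_post(dw$start) ~ "post",
                                TRUE ~ NA_character_)
  dw <- dw[!is.na(dw$window), ]
  per_topic <- dw |>
    dplyr::group_by(topic_id = .data$topic_id, window = .data$window) |>
    dplyr::summarise(
      n_views = dplyr::n(),
      unique_terms = dplyr::n_distinct(.data$initiating_term[!is.na(.data$initiating_term)]),
      long_click_proportion = mean(.data$label == "long"),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "window",
                       values_from = c("n_views", "unique_terms", "long_click_proportion"),
                       values_fill = list(n_views = 0L, unique_terms = 0L))

  has_spec <- query_matches(drug_searches$payload, specificity_set, lex)
  structure(list(
    alert_date = alert_date,
    topics = per_topic,
    pre_mean_dwell = mean(dw$duration[dw$window == "pre"]),
    post_mean_dwell = mean(dw$duration[dw$window == "post"]),
    pre_unique_terms = dplyr::n_distinct(
      dw$initiating_term[dw$window == "pre" & !is.na(dw$initiating_term)]),
    post_unique_terms = dplyr::n_distinct(
      dw$initiating_term[dw$window == "post" & !is.na(dw$initiating_term)]),
    specificity_pre = sum(has_spec & in_pre(drug_searches$timestamp)),
    specificity_post = sum(has_spec & in_post(drug_searches$timestamp)),
    boundary_seconds = if (inherits(boundary, "click_boundary")) boundary$boundary_seconds else boundary,
    window = c(pre_start = lo, post_end = hi)
  ), class = "alert_report")
}

#' @export
print.alert_report <- function(x, ...) {
  cat(sprintf("<alert report: alert %s>\n", format(x$alert_date)))
  cat(sprintf("  unique initiating terms: %d pre -> %d post\n",
              x$pre_unique_terms, x$post_unique_terms))
  cat(sprintf("  mean dwell on drug topics: %.1f s pre -> %.1f s post\n",
              x$pre_mean_dwell, x$post_mean_dwell))
  cat(sprintf("  drug+specificity searches: %d pre -> %d post\n",
              x$specificity_pre, x$specificity_post))
  invisible(x)
}
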