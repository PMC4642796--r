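# Topic identifier of a view event: subtopic views carry
# "parent_topic/suffix" payloads and inherit the parent topic.
parent_topic <- function(payload, action) {
  ifelse(action == "subtopic_view",
         stringr::str_replace(payload, "/.*$", ""),
         payload)
}

#' Compute topic-view dwell times for a whole log
#'
#' A dwell is a maximal block of consecutive views of the same topic within
#' a session (subtopic views inherit their parent topic and do not break
#' the block). The block's duration runs from its first view to the next
#' event that terminates it — a search or a view of a different topic. A
#' block terminated by nothing (the session's final events) is dropped, as
#' are zero-length blocks. Each dwell is attributed to the nearest
#' preceding search in the session (normalized query), absent if none.
#'
#' @param events A `log_events` tibble covering one or more sessions.
#' @return A tibble with columns `session_id`, `topic_id`, `start`
#'   (POSIXct), `duration` (seconds), `initiating_term` (NA if none) and
#'   `label` (all `"unclassified"`).
#' @export
dwell_table <- function(events) {
  ev <- tibble::as_tibble(events)
  empty <- tibble::tibble(session_id = character(0), topic_id = character(0),
                          start = as.POSIXct(character(0), tz = "UTC"),
                          duration = numeric(0), initiating_term = character(0),
                          label = character(0))
  if (nrow(ev) == 0) return(empty)
  ev$.input_order <- seq_len(nrow(ev))
  ord <- order(ev$session_id, ev$timestamp, ev$.input_order)
  ev <- ev[ord, ]
  n <- nrow(ev)
  is_view <- ev$action != "search"
  topic <- ifelse(is_view, parent_topic(ev$payload, ev$action), NA_character_)
  new_session <- c(TRUE, ev$session_id[-1] != ev$session_id[-n])

  # forward-fill the most recent search payload within each session
  search_norm <- ifelse(is_view, NA_character_, normalize_text(ev$payload))
  # positions of the governing search for each row (last non-NA, reset per session)
  idx <- seq_len(n)
  last_search <- rep(NA_integer_, n)
  cur <- NA_integer_
  for (i in idx) {
    if (new_session[i]) cur <- NA_integer_
    if (!is_view[i]) cur <- i
    last_search[i] <- cur
  }

  prev_is_view <- c(FALSE, is_view[-n])
  prev_topic <- c(NA_character_, topic[-n])
  block_start <- is_view & (new_session | !prev_is_view |
                              is.na(prev_topic) | prev_topic != topic)
  block_id <- cumsum(block_start)
  block_id[!is_view] <- NA_integer_

  view_rows <- which(is_view)
  if (length(view_rows) == 0) return(empty)
  firsts <- view_rows[block_start[view_rows]]
  # last row of each block = row before the next block's first row among views
  blk <- block_id[view_rows]
  lasts <- view_rows[c(which(diff(blk) != 0), length(view_rows))]
  term_row <- lasts + 1L
  terminated <- term_row <= n & !new_session[pmin(term_row, n)]
  keep <- which(terminated)
  start_ts <- ev$timestamp[firsts[keep]]
  dur <- as.numeric(difftime(ev$timestamp[term_row[keep]], start_ts, units = "secs"))
  init_row <- last_search[firsts[keep]]
  out <- tibble::tibble(
    session_id = ev$session_id[firsts[keep]],
    topic_id = topic[firsts[keep]],
    start = start_ts,
    duration = dur,
    initiating_term = ifelse(is.na(init_row), NA_character_, search_norm[init_row]),
    label = "unclassified"
  )
  out[out$duration > 0, ]
}

#' Compute dwell times for a single session
#'
#' Single-session interface to [dwell_table()].
#'
#' @param session A time-ordered tibble of one session's events.
#' @return See [dwell_table()].
#' @export
compute_dwells <- function(session) {
  stopifnot(length(unique(session$session_id)) <= 1)
  dwell_table(session)
}

#' Fit the short/long click boundary
#'
#' The decision boundary is the mean of the log-transformed dwell
#' durations, converted back to seconds — the geometric mean. The log base
#' cancels in the back-transform, so it does not affect the result.
#'
#' @param durations Positive dwell durations in seconds.
#' @return A list of class `click_boundary` with `boundary_seconds` and
#'   `n_durations`.
#' @export
fit_boundary <- function(durations) {
  durations <- as.numeric(durations)
  if (length(durations) == 0) stop("cannot fit a boundary on zero durations")
  if (any(!is.finite(durations) | durations <= 0)) {
    stop("all durations must be finite and positive")
  }
  structure(list(boundary_seconds = exp(mean(log(durations))),
                 n_durations = length(durations)),
            class = "click_boundary")
}

#' @export
print.click_boundary <- function(x, ...) {
  cat(sprintf("<click boundary: %.2f s (fit on %d durations)>\n",
              x$boundary_seconds, x$n_durations))
  invisible(x)
}

#' Classify dwell durations as short or long clicks
#'
#' Long iff the duration exceeds the boundary; a duration exactly at the
#' boundary is short (the defining rule uses "less than" for short and
#' "above" for long, leaving equality to the implementation).
#'
#' @param durations Positive durations in seconds.
#' @param boundary A [fit_boundary()] result or a number of seconds.
#' @return Character vector of `"short"`/`"long"`.
#' @export
classify_clicks <- function(durations, boundary) {
  b <- if (inherits(boundary, "click_boundary")) boundary$boundary_seconds else boundary
  stopifnot(is.numeric(b), b > 0)
  if (any(durations <= 0)) stop("durations must be positive")
  ifelse(durations > b, "long", "short")
}

#' Label a dwell table with short/long clicks
#'
#' @param dwells A [dwell_table()] result.
#' @param boundary A [fit_boundary()] result or a number of seconds; if
#'   missing, fit on these dwells.
#' @return `dwells` with the `label` column filled in.
#' @export
label_dwells <- function(dwells, boundary = NULL) {
  if (is.null(boundary)) boundary <- fit_boundary(dwells$duration)
  dwells$label <- classify_clicks(dwells$duration, boundary)
  dwells
}

#' Per-topic engagement summary
#'
#' For each topic: number of labeled dwells, proportion of long clicks, and
#' the number of unique search terms that initiated views of the topic.
#'
#' @param dwells A labeled dwell table.
#' @return A tibble with columns `topic_id`, `n_views`,
#'   `long_click_proportion`, `n_unique_initiating_terms`.
#' @export
topic_engagement <- function(dwells) {
  stopifnot(all(dwells$label %in% c("short", "long")))
  dwells |>
    dplyr::group_by(topic_id = .data$topic_id) |>
    dplyr::summarise(
      n_views = dplyr::n(),
      long_click_proportion = mean(.data$label == "long"),
      n_unique_initiating_terms = dplyr::n_distinct(.data$initiating_term[!is.na(.data$initiating_term)]),
      .groups = "drop"
    )
}

#' Per-search-term engagement summary
#'
#' Symmetric to [topic_engagement()], keyed by initiating search term:
#' proportion of long clicks among dwells the term initiated and the number
#' of distinct topics it led to. Dwells with no initiating search are
#' excluded.
#'
#' @param dwells A labeled dwell table.
#' @return A tibble with columns `term`, `n_views`,
#'   `long_click_proportion`, `n_unique_topics`.
#' @export
term_engagement <- function(dwells) {
  stopifnot(all(dwells$label %in% c("short", "long")))
  dwells[!is.na(dwells$initiating_term), ] |>
    dplyr::group_by(term = .data$initiating_term) |>
    dplyr::summarise(
      n_views = dplyr::n(),
      long_click_proportion = mean(.data$label == "long"),
      n_unique_topics = dplyr::n_distinct(.data$topic_id),
      .groups = "drop"
    )
}

#' Hampel identifier bounds
#'
#' Robust outlier thresholds: median plus/minus `k` times the
#' Gaussian-consistent MAD (scale constant 1.4826). Used to split
#' long-click proportions into low/typical/high regimes, in which case the
#' bounds are clamped to \[0, 1\].
#'
#' @param values Numeric vector (at least 2 values).
#' @param k Multiplier, default 3.
#' @param clamp Optional `c(lo, hi)` interval to clamp the bounds to.
#' @return A list of class `hampel_bounds` with `low`, `high`, `median`,
#'   `scaled_mad`, `degenerate`.
#' @export
hampel_bounds <- function(values, k = 3, clamp = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values for Hampel bounds")
  m <- stats::median(values)
  s <- stats::mad(values, constant = 1.4826)
  low <- m - k * s
  high <- m + k * s
  if (!is.null(clamp)) {
    low <- max(low, clamp[1]); high <- min(high, clamp[2])
  }
  structure(list(low = low, high = high, median = m, scaled_mad = s,
                 degenerate = s == 0),
            class = "hampel_bounds")
}

#' @export
print.hampel_bounds <- function(x, ...) {
  cat(sprintf("<Hampel bounds: low %.4g, high %.4g (median %.4g, scaled MAD %.4g)%s>\n",
              x$low, x$high, x$median, x$scaled_mad,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Compare unique initiating-term counts between engagement groups
#'
#' Mann-Whitney U test between two groups of per-topic counts (e.g., topics
#' with high vs low long-click proportion), with descriptive statistics.
#' Exact enumeration is used for small samples (both groups of size 8 or
#' fewer, no ties); otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param high_group,low_group Numeric vectors of counts.
#' @return A list with `U`, `p_value`, `method`, and a `descriptives`
#'   tibble (group, n, mean, sd, median, iqr).
#' @export
compare_initiating_term_counts <- function(high_group, low_group) {
  if (length(high_group) == 0 || length(low_group) == 0) {
    stop("both groups must be non-empty")
  }
  ties <- any(duplicated(c(high_group, low_group)))
  exact <- length(high_group) <= 8 && length(low_group) <= 8 && !ties
  wt <- stats::wilcox.test(high_group, low_group, exact = exact,
                           correct = !exact, alternative = "two.sided")
  desc <- dplyr::bind_rows(
    tibble::tibble(group = "high", n = length(high_group),
                   mean = mean(high_group), sd = stats::sd(high_group),
                   median = stats::median(high_group), iqr = stats::IQR(high_group)),
    tibble::tibble(group = "low", n = length(low_group),
                   mean = mean(low_group), sd = stats::sd(low_group),
                   median = stats::median(low_group), iqr = stats::IQR(low_group))
  )
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation",
       descriptives = desc)
}
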