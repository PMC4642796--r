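#' Extract topic-view runs from a session
#'
#' A run is a maximal stretch of consecutive topic/subtopic views
#' uninterrupted by a search. Subtopic views map to their parent topic and
#' immediately repeated identical topics are collapsed (subtopic clicks
#' within one page would otherwise manufacture spurious repeat patterns).
#' Each run carries the normalized payload of the search immediately
#' preceding it, `NA` if the run opens the session.
#'
#' @param session A time-ordered tibble of one session's events.
#' @return A list of runs, each `list(topics = <character>, initiator =
#'   <string or NA>)`.
#' @export
topic_runs <- function(session) {
  ev <- tibble::as_tibble(session)
  if (nrow(ev) == 0) return(list())
  is_view <- ev$action != "search"
  topic <- ifelse(is_view, parent_topic(ev$payload, ev$action), NA_character_)
  runs <- list()
  cur <- character(0)
  initiator <- NA_character_
  pending_initiator <- NA_character_
  for (i in seq_len(nrow(ev))) {
    if (is_view[i]) {
      if (length(cur) == 0) initiator <- pending_initiator
      if (length(cur) == 0 || cur[length(cur)] != topic[i]) cur <- c(cur, topic[i])
    } else {
      if (length(cur) > 0) {
        runs[[length(runs) + 1]] <- list(topics = cur, initiator = initiator)
        cur <- character(0)
      }
      pending_initiator <- normalize_text(ev$payload[i])
    }
  }
  if (length(cur) > 0) runs[[length(runs) + 1]] <- list(topics = cur, initiator = initiator)
  runs
}

#' Mine frequent contiguous topic-view sequences
#'
#' Every contiguous subsequence (sliding window) of length `min_len` to
#' `max_len` of every run is counted once per occurrence; the run's
#' initiating search term is credited to each of its windows. Runs with no
#' preceding search contribute to counts but not to initiating-term
#' tallies.
#'
#' @param sessions A list of session tibbles (see [group_sessions()]), or a
#'   `log_events` tibble (grouped internally).
#' @param min_len,max_len Window length bounds (defaults 2 and 4; beyond
#'   length 4 sequences are dominated by back-and-forth topic switching).
#' @return A tibble with columns `topics` (list-column), `key`
#'   (pipe-joined topics), `length`, `count`, `initiating_terms`
#'   (list-column of named integer vectors).
#' @export
mine_sequences <- function(sessions, min_len = 2, max_len = 4) {
  stopifnot(min_len >= 2, max_len >= min_len)
  if (is.data.frame(sessions)) sessions <- group_sessions(sessions)
  keys <- character(0)
  initiators <- character(0)
  for (s in sessions) {
    for (run in topic_runs(s)) {
      L <- length(run$topics)
      for (len in min_len:max_len) {
        if (L < len) break
        for (i in seq_len(L - len + 1L)) {
          keys[length(keys) + 1L] <- paste(run$topics[i:(i + len - 1L)], collapse = "|")
          initiators[length(initiators) + 1L] <-
            if (is.na(run$initiator)) NA_character_ else run$initiator
        }
      }
    }
  }
  if (length(keys) == 0) {
    return(tibble::tibble(topics = list(), key = character(0), length = integer(0),
                          count = integer(0), initiating_terms = list()))
  }
  df <- tibble::tibble(key = keys, initiator = initiators)
  counts <- df |> dplyr::count(.data$key, name = "count")
  term_tallies <- df[!is.na(df$initiator), ] |>
    dplyr::count(.data$key, .data$initiator, name = "n")
  tally_by_key <- split(term_tallies, term_tallies$key)
  counts$initiating_terms <- lapply(counts$key, function(k) {
    t <- tally_by_key[[k]]
    if (is.null(t)) return(stats::setNames(integer(0), character(0)))
    stats::setNames(as.integer(t$n), t$initiator)
  })
  counts$topics <- strsplit(counts$key, "|", fixed = TRUE)
  counts$length <- lengths(counts$topics)
  counts[, c("topics", "key", "length", "count", "initiating_terms")]
}

#' Topic-switching fraction of a sequence pattern
#'
#' Measures back-and-forth navigation: the fraction of positions `i` with
#' `topics[i] == topics[i + 2]`. Pure alternation between two topics
#' (A,B,A\[,B\]) scores 1; sequences of length 2, or with no such repeat
#' structure, score 0.
#'
#' @param topics Character vector of topic IDs, length at least 2.
#' @return A proportion in \[0, 1\].
#' @export
switching_fraction <- function(topics) {
  L <- length(topics)
  stopifnot(L >= 2)
  if (L < 3) return(0)
  mean(topics[seq_len(L - 2)] == topics[seq_len(L - 2) + 2L])
}

#' Top-ranked sequence patterns
#'
#' The `k` most frequent patterns among the requested lengths, ties broken
#' lexicographically by topic tuple for determinism, each with its top-5
#' initiating terms by count (term ties also lexicographic).
#'
#' @param patterns A [mine_sequences()] result.
#' @param k Number of patterns to return (positive).
#' @param lengths Optional vector of pattern lengths to keep.
#' @return The ranked subset, with an added `top_terms` list-column of the
#'   top-5 named term counts.
#' @export
top_patterns <- function(patterns, k, lengths = NULL) {
  if (k <= 0) stop("k must be positive")
  p <- patterns
  if (!is.null(lengths)) p <- p[p$length %in% lengths, ]
  p <- p[order(-p$count, p$key), ]
  p <- utils::head(p, k)
  p$top_terms <- lapply(p$initiating_terms, function(tt) {
    if (length(tt) == 0) return(tt)
    tt <- tt[order(-tt, names(tt))]
    utils::head(tt, 5)
  })
  p
}
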