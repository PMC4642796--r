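# Independent brute-force oracles. These deliberately use naive
# event-by-event scans (different code paths from the package's vectorized
# implementations) so equivalence tests are meaningful.

# dwell oracle: for every view event that starts a block, scan forward for
# the terminating event
oracle_dwells <- function(session) {
  ev <- session[order(session$timestamp), ]  # order() is stable
  n <- nrow(ev)
  topic_of <- function(i) {
    if (ev$action[i] == "search") return(NA_character_)
    if (ev$action[i] == "subtopic_view") sub("/.*$", "", ev$payload[i]) else ev$payload[i]
  }
  out <- list()
  i <- 1
  while (i <= n) {
    if (ev$action[i] == "search") { i <- i + 1; next }
    blk_topic <- topic_of(i)
    j <- i + 1
    while (j <= n && ev$action[j] != "search" && identical(topic_of(j), blk_topic)) j <- j + 1
    if (j <= n) {
      dur <- as.numeric(difftime(ev$timestamp[j], ev$timestamp[i], units = "secs"))
      init <- NA_character_
      for (k in seq_len(i - 1)) {
        if (ev$action[k] == "search") init <- clicklog::normalize_text(ev$payload[k])
      }
      if (dur > 0) {
        out[[length(out) + 1]] <- data.frame(
          session_id = ev$session_id[i], topic_id = blk_topic,
          start = ev$timestamp[i], duration = dur,
          initiating_term = init, stringsAsFactors = FALSE)
      }
    }
    i <- j
  }
  if (length(out) == 0) {
    return(data.frame(session_id = character(0), topic_id = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      duration = numeric(0), initiating_term = character(0)))
  }
  do.call(rbind, out)
}

# run oracle: accumulate view stretches between searches, collapsing repeats
oracle_runs <- function(session) {
  ev <- session[order(session$timestamp), ]
  runs <- list(); cur <- character(0); init <- NA_character_; pend <- NA_character_
  for (i in seq_len(nrow(ev))) {
    if (ev$action[i] == "search") {
      if (length(cur)) { runs[[length(runs) + 1]] <- list(topics = cur, initiator = init); cur <- character(0) }
      pend <- clicklog::normalize_text(ev$payload[i])
    } else {
      t <- if (ev$action[i] == "subtopic_view") sub("/.*$", "", ev$payload[i]) else ev$payload[i]
      if (!length(cur)) init <- pend
      if (!length(cur) || tail(cur, 1) != t) cur <- c(cur, t)
    }
  }
  if (length(cur)) runs[[length(runs) + 1]] <- list(topics = cur, initiator = init)
  runs
}

# subsequence-count oracle via an environment hash
oracle_mine <- function(sessions, min_len = 2, max_len = 4) {
  counts <- new.env(); terms <- new.env()
  for (s in sessions) for (run in oracle_runs(s)) {
    L <- length(run$topics)
    for (len in min_len:max_len) {
      if (L < len) next
      for (i in 1:(L - len + 1)) {
        key <- paste(run$topics[i:(i + len - 1)], collapse = "|")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
        if (!is.na(run$initiator)) {
          tk <- paste0(key, "\r", run$initiator)
          terms[[tk]] <- (terms[[tk]] %||% 0L) + 1L
        }
      }
    }
  }
  list(counts = counts, terms = terms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_moving_average <- function(x, w) {
  n <- length(x); out <- rep(NA_real_, n)
  for (i in w:n) out[i] <- mean(x[(i - w + 1):i])
  out
}

# maximal-match annotation oracle: at each token position try every lexicon
# term, keep the longest that matches
oracle_annotate_terms <- function(norm_query, all_terms) {
  toks <- strsplit(norm_query, " ", fixed = TRUE)[[1]]
  if (!nzchar(norm_query)) return(character(0))
  found <- character(0); i <- 1
  while (i <= length(toks)) {
    best <- NULL; best_len <- 0
    for (term in all_terms) {
      tt <- strsplit(term, " ", fixed = TRUE)[[1]]
      L <- length(tt)
      if (L > best_len && i + L - 1 <= length(toks) &&
          identical(toks[i:(i + L - 1)], tt)) {
        best <- term; best_len <- L
      }
    }
    if (is.null(best)) i <- i + 1 else { found <- c(found, best); i <- i + best_len }
  }
  found
}

# one-hop term-set expansion oracle over the raw term-concept pairs
oracle_expand <- function(seeds, term_concepts, exclusions = character(0)) {
  out <- seeds
  for (s in seeds) {
    cids <- term_concepts$concept_id[term_concepts$term == s]
    for (cid in cids) out <- c(out, term_concepts$term[term_concepts$concept_id == cid])
  }
  setdiff(unique(out), exclusions)
}

# exact two-sided Mann-Whitney p by full enumeration over assignments
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b); n <- length(a); m <- length(b)
  idx <- utils::combn(n + m, n)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  u_obs <- u_of(a, b)
  umin <- min(u_obs, n * m - u_obs); umax <- n * m - umin
  mean(us <= umin) + mean(us >= umax)
}

# adversarial random event tables: timestamp ties, repeated topics,
# subtopics, sessions ending in views
random_events <- function(n_events, n_sessions, seed, n_topics = 6, vocab = letters[1:5]) {
  withr::with_seed(seed, {
    actions <- sample(c("search", "topic_view", "subtopic_view"), n_events,
                      replace = TRUE, prob = c(0.3, 0.5, 0.2))
    topics <- paste0("T", sample.int(n_topics, n_events, replace = TRUE))
    payload <- ifelse(actions == "search",
                      sample(vocab, n_events, replace = TRUE),
                      ifelse(actions == "subtopic_view", paste0(topics, "/s1"), topics))
    clicklog::log_events(
      session_id = paste0("s", sample.int(n_sessions, n_events, replace = TRUE)),
      institution_id = "inst1",
      timestamp = as.POSIXct("2011-06-01", tz = "UTC") +
        sample.int(n_events * 2, n_events, replace = TRUE),
      action = actions, payload = payload)
  })
}

# a small deterministic lexicon fixture shared across tests
fixture_lexicon <- function() {
  tc <- tibble::tibble(
    term = c("celexa", "citalopram", "tamiflu", "influenza", "flu",
             "diabetes", "diabetes insipidus",
             "essential hypertension nos", "hypertensive disease",
             "high blood pressure", "long qt", "heart", "rhythm"),
    concept_id = c("c_cit", "c_cit", "c_oselt", "c_flu", "c_flu",
                   "c_dm", "c_di",
                   "c_htn", "c_htn", "c_htn", "c_lqt", "c_heart", "c_rhythm"))
  cats <- c(c_cit = "drug", c_oselt = "drug", c_flu = "disease_symptom",
            c_dm = "disease_symptom", c_di = "disease_symptom",
            c_htn = "disease_symptom", c_lqt = "disease_symptom",
            c_heart = "disease_symptom", c_rhythm = "disease_symptom")
  clicklog::lexicon(tc, cats,
                    tibble::tibble(parent = "c_dm", child = "c_di"))
}

# random lexicons for property tests: terms built from a syllable pool so
# multiword terms decompose into tokens that may themselves be terms
random_lexicon_df <- function(n_concepts, seed) {
  withr::with_seed(seed, {
    pool <- apply(expand.grid(c("ka", "lo", "mi", "ru", "ze"),
                              c("na", "ti", "vo", "su")), 1, paste, collapse = "")
    rows <- lapply(seq_len(n_concepts), function(i) {
      n_syn <- sample(1:3, 1)
      terms <- vapply(seq_len(n_syn), function(j) {
        paste(sample(pool, sample(1:3, 1), replace = TRUE), collapse = " ")
      }, "")
      tibble::tibble(term = unique(terms), concept_id = paste0("c", i),
                     category = sample(c("disease_symptom", "drug", "device",
                                         "procedure", "none"), 1))
    })
    dplyr::bind_rows(rows)
  })
}

lexicon_from_df <- function(df) {
  cat_by <- unique(df[, c("concept_id", "category")])
  clicklog::lexicon(df[, c("term", "concept_id")],
                    stats::setNames(cat_by$category, cat_by$concept_id))
}
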