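#' Configuration for the synthetic-data generator
#'
#' Defaults emulate a two-year usage log around a drug-safety alert: daily
#' session volume is Poisson; each session is one free-text search followed
#' by 1-6 topic/subtopic views; dwell gaps are drawn from a two-class
#' log-normal mixture attached to search terms (so a term yields
#' consistently short or consistently long clicks); a designated seasonal
#' term set carries a sinusoidal annual volume modulation; a designated
#' drug term set carries a delayed, sustained alert response (search rate
#' multiplied from `alert$date + lag_days` for `elevated_duration_days`,
#' query vocabulary broadened, post-alert dwell means shifted down); and
#' the matching media stream spikes immediately at the alert and decays
#' geometrically.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param ... Named overrides of the defaults listed below.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    span = as.Date(c("2011-01-01", "2012-12-31")),
    tz = "UTC",
    sessions_per_day = 150,
    views_per_session = c(0.25, 0.25, 0.20, 0.15, 0.10, 0.05),
    dwell = list(meanlog_short = log(30), meanlog_long = log(600), sdlog = 0.8),
    frac_long_terms = 0.5,
    n_background_concepts = 60,
    n_institutions = 25,
    p_follow = 0.5,
    p_subtopic = 0.5,
    p_final_search = 0.5,
    motif_boost = 8,
    seasonal = list(base_prob = 0.05, amplitude = 0.6, peak_month = 1),
    alert = list(date = as.Date("2011-08-24"), base_prob = 0.05, lag_days = 10,
                 effect_multiplier = 5, elevated_duration_days = 60,
                 vocab_broadening_factor = 3, dwell_shift = -0.12,
                 spec_pre_prob = 0.02),
    media = list(base_rate = 5, noise_rate = 20, spike_day_offset = 0,
                 spike_height = 30, decay_days = 10),
    category_mix = c(disease_symptom = 0.70, drug = 0.20,
                     device = 0.05, procedure = 0.05)
  )
  dots <- list(...)
  for (i in seq_along(dots)) {  # later duplicates win, so wrappers can layer overrides
    nm <- names(dots)[i]
    if (is.null(nm) || !nm %in% names(cfg)) stop("unknown generator_config field: ", nm)
    if (is.list(cfg[[nm]]) && is.list(dots[[i]])) {
      cfg[[nm]][names(dots[[i]])] <- dots[[i]]
    } else {
      cfg[[nm]] <- dots[[i]]
    }
  }
  stopifnot(cfg$sessions_per_day >= 0, cfg$dwell$sdlog > 0,
            cfg$alert$lag_days >= 0, cfg$frac_long_terms >= 0,
            cfg$frac_long_terms <= 1,
            abs(sum(cfg$category_mix) - 1) < 1e-9)
  if (cfg$alert$date < cfg$span[1] || cfg$alert$date > cfg$span[2]) {
    stop("alert date outside the generated span")
  }
  class(cfg) <- "generator_config"
  cfg
}

# deterministic designated clusters present in every generated lexicon
designated_concepts <- function() {
  list(
    list(id = "c_citalopram", category = "drug",
         terms = c("celexa", "citalopram"), parent = ""),
    list(id = "c_long_qt", category = "disease_symptom",
         terms = c("long qt", "prolonged qt"), parent = ""),
    list(id = "c_heart", category = "disease_symptom",
         terms = c("heart"), parent = ""),
    list(id = "c_rhythm", category = "disease_symptom",
         terms = c("rhythm"), parent = ""),
    list(id = "c_dose", category = "none",
         terms = c("dose", "dosage"), parent = ""),
    list(id = "c_influenza", category = "disease_symptom",
         terms = c("influenza", "flu"), parent = ""),
    list(id = "c_oseltamivir", category = "drug",
         terms = c("tamiflu", "oseltamivir"), parent = "c_influenza"),
    list(id = "c_hypertensive_disease", category = "disease_symptom",
         terms = c("essential hypertension nos", "hypertensive disease",
                   "high blood pressure"), parent = "")
  )
}

alert_terms <- function() c("celexa", "citalopram")
specificity_terms <- function() c("long qt", "heart", "rhythm")
seasonal_terms <- function() c("influenza", "flu")

alert_query_vocab <- function(cfg) {
  base <- alert_terms()
  modifiers <- c(specificity_terms(), "dose")
  extra <- as.vector(t(outer(base, modifiers, paste)))
  n_broad <- max(length(base),
                 ceiling(cfg$alert$vocab_broadening_factor * length(base)))
  list(base = base, broadened = c(base, utils::head(extra, n_broad - length(base))))
}

#' Generate a synthetic lexicon
#'
#' Deterministic given the config seed: designated clusters (the alert
#' drug and its adverse-event vocabulary, a seasonal disease/drug pair, a
#' multi-synonym expansion demonstration cluster) plus
#' `n_background_concepts` background concepts with 1-5 synonyms each,
#' categories allocated to the configured category mix, and a shallow
#' acyclic parent hierarchy.
#'
#' @param cfg A [generator_config()].
#' @return A list with `lex` (a [lexicon()]) and `meta` (per-concept
#'   category/terms bookkeeping used by [gen_logs()]).
#' @export
gen_lexicon <- function(cfg) {
  withr::with_seed(cfg$seed, {
    cats <- names(cfg$category_mix)
    n <- cfg$n_background_concepts
    if (n < 2 * length(cats)) stop("need at least ", 2 * length(cats), " background concepts")
    # guarantee two concepts per category, fill the rest by the mix
    cat_assign <- c(rep(cats, 2),
                    sample(cats, n - 2 * length(cats), replace = TRUE,
                           prob = cfg$category_mix))
    cat_assign <- sample(cat_assign)  # shuffle positions
    rows <- list()
    meta <- list()
    for (d in designated_concepts()) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        concept_id = d$id, term = d$terms, category = d$category, parent = d$parent)
      meta[[d$id]] <- list(category = d$category, terms = d$terms)
    }
    stem <- function(i) sprintf("bg%02d", i)
    for (i in seq_len(n)) {
      cid <- paste0("c_", stem(i))
      n_syn <- sample(1:5, 1)
      syn_suffixes <- c("", " nos", " disorder", " unspecified", " chronic")
      terms <- paste0(stem(i), syn_suffixes[seq_len(n_syn)])
      parent <- if (i > 1 && runif(1) < 0.3) paste0("c_", stem(sample(i - 1, 1))) else ""
      rows[[length(rows) + 1]] <- tibble::tibble(
        concept_id = cid, term = terms, category = cat_assign[i], parent = parent)
      meta[[cid]] <- list(category = cat_assign[i], terms = terms)
    }
    df <- dplyr::bind_rows(rows)
    with_parent <- df[nzchar(df$parent), ]
    hier <- dplyr::distinct(tibble::tibble(parent = with_parent$parent,
                                           child = with_parent$concept_id))
    cat_by <- dplyr::distinct(df[, c("concept_id", "category")])
    lex <- lexicon(df[, c("term", "concept_id")],
                   stats::setNames(cat_by$category, cat_by$concept_id), hier)
    list(lex = lex, meta = meta)
  })
}

#' Generate a synthetic usage log with planted ground truth
#'
#' See [generator_config()] for the generative model. The returned ground
#' truth records *realized* quantities (per-term dwell class, per-day
#' matched/total search counts, the planted alert window, the boosted
#' sequence motif, the category mix), so downstream tests never re-derive
#' planted values from the log itself.
#'
#' @param cfg A [generator_config()].
#' @param lexgen Optional result of [gen_lexicon()] (regenerated from the
#'   config when NULL).
#' @return A list with `events` (a `log_events` tibble), `lex`, and
#'   `truth`.
#' @export
gen_logs <- function(cfg, lexgen = NULL) {
  if (is.null(lexgen)) lexgen <- gen_lexicon(cfg)
  lex <- lexgen$lex
  meta <- lexgen$meta
  withr::with_seed(cfg$seed + 1L, {
    days <- seq(cfg$span[1], cfg$span[2], by = "day")
    nd <- length(days)
    onset <- cfg$alert$date + cfg$alert$lag_days
    elev_days <- days >= onset & days < onset + cfg$alert$elevated_duration_days
    month <- as.integer(format(days, "%m"))
    p_seasonal <- cfg$seasonal$base_prob *
      (1 + cfg$seasonal$amplitude * cos(2 * pi * (month - cfg$seasonal$peak_month) / 12))
    p_alert <- cfg$alert$base_prob * ifelse(elev_days, cfg$alert$effect_multiplier, 1)
    if (any(p_alert + p_seasonal >= 1)) stop("stream probabilities exceed 1; lower base rates")

    n_sess <- rpois(nd, cfg$sessions_per_day)
    S <- sum(n_sess)
    vocab <- alert_query_vocab(cfg)

    # per-term dwell class: background and seasonal terms split by
    # frac_long_terms; alert queries are all-long (shifted post alert)
    bg_ids <- grep("^c_bg", names(meta), value = TRUE)
    bg_terms <- unlist(lapply(meta[bg_ids], `[[`, "terms"), use.names = FALSE)
    classed_terms <- c(bg_terms, seasonal_terms())
    term_class <- stats::setNames(
      ifelse(runif(length(classed_terms)) < cfg$frac_long_terms, "long", "short"),
      classed_terms)
    term_class[c(vocab$base, vocab$broadened)] <- "long"

    empty_truth <- list(term_class = term_class, daily = NULL, alert = NULL)
    if (S == 0) {
      ev <- log_events(character(0), character(0),
                       as.POSIXct(character(0), tz = cfg$tz),
                       character(0), character(0))
      return(list(events = ev, lex = lex,
                  truth = c(empty_truth, list(note = "empty log"))))
    }

    day_idx <- rep(seq_len(nd), n_sess)
    sess_date <- days[day_idx]
    sess_start <- as.POSIXct(sess_date, tz = cfg$tz) + floor(runif(S, 0, 82800))
    sess_id <- paste0("s", seq_len(S))
    inst <- paste0("inst", sample.int(cfg$n_institutions, S, replace = TRUE))

    u <- runif(S)
    stream <- rep("background", S)
    stream[u < (p_alert + p_seasonal)[day_idx]] <- "seasonal"
    stream[u < p_alert[day_idx]] <- "alert"

    # concept sampling weights for background searches: category mix exact,
    # uniform within category except the boosted motif concept
    bg_cat <- vapply(meta[bg_ids], `[[`, "", "category")
    disease_ids <- bg_ids[bg_cat == "disease_symptom"]
    drug_ids <- bg_ids[bg_cat == "drug"]
    motif_disease <- disease_ids[1]
    motif_drug <- drug_ids[1]
    w <- numeric(length(bg_ids))
    for (cat in unique(bg_cat)) {
      in_cat <- bg_cat == cat
      wc <- rep(1, sum(in_cat))
      if (cat == "disease_symptom") wc[which(bg_ids[in_cat] == motif_disease)] <- cfg$motif_boost
      w[in_cat] <- cfg$category_mix[[cat]] * wc / sum(wc)
    }

    query <- character(S)
    sess_concept <- character(S)
    is_bg <- stream == "background"
    if (any(is_bg)) {
      ci <- sample.int(length(bg_ids), sum(is_bg), replace = TRUE, prob = w)
      sess_concept[is_bg] <- bg_ids[ci]
      term_lists <- lapply(meta[bg_ids], `[[`, "terms")
      n_syn <- lengths(term_lists)
      flat_terms <- unlist(term_lists, use.names = FALSE)
      term_offset <- cumsum(c(0L, n_syn[-length(n_syn)]))
      syn_i <- floor(runif(sum(is_bg)) * n_syn[ci]) + 1L
      query[is_bg] <- flat_terms[term_offset[ci] + syn_i]
    }
    is_seas <- stream == "seasonal"
    if (any(is_seas)) {
      query[is_seas] <- sample(seasonal_terms(), sum(is_seas), replace = TRUE)
      sess_concept[is_seas] <- "c_influenza"
    }
    is_alert <- stream == "alert"
    if (any(is_alert)) {
      broadened <- elev_days[day_idx[is_alert]] |
        runif(sum(is_alert)) < cfg$alert$spec_pre_prob
      qa <- character(sum(is_alert))
      qa[broadened] <- sample(vocab$broadened, sum(broadened), replace = TRUE)
      qa[!broadened] <- sample(vocab$base, sum(!broadened), replace = TRUE)
      query[is_alert] <- qa
      sess_concept[is_alert] <- "c_citalopram"
    }

    # dwell class per session: the searched term's planted class
    sess_class <- unname(term_class[query])
    sess_class[is_alert] <- "long"
    sess_class[is.na(sess_class)] <- "short"
    meanlog <- rep(cfg$dwell$meanlog_short, S)
    meanlog[sess_class == "long"] <- cfg$dwell$meanlog_long
    post_alert <- sess_date >= cfg$alert$date
    meanlog <- meanlog + ifelse(is_alert & post_alert, cfg$alert$dwell_shift, 0)

    # topics: first view on the session concept's topic; later views follow
    # a planted disease->drug transition with prob p_follow, else random
    trans <- stats::setNames(bg_ids[pmax(1, (seq_along(bg_ids) %% length(bg_ids)) + 1L)], bg_ids)
    trans[disease_ids] <- sample(drug_ids, length(disease_ids), replace = TRUE)
    trans[motif_disease] <- motif_drug
    trans["c_influenza"] <- "c_oseltamivir"
    trans["c_citalopram"] <- "c_citalopram"
    trans["c_oseltamivir"] <- "c_oseltamivir"

    V <- sample.int(6L, S, replace = TRUE, prob = cfg$views_per_session)
    TV <- sum(V)
    vs <- rep(seq_len(S), V)
    pos <- sequence(V)
    topic_concept <- character(TV)
    first <- pos == 1L
    topic_concept[first] <- sess_concept[vs[first]]
    later <- !first
    if (any(later)) {
      # alert-drug sessions stay on the drug's pages (a drug-information
      # lookup, not exploratory browsing); others follow the planted
      # disease->treatment transition with prob p_follow
      follow <- runif(sum(later)) < cfg$p_follow | is_alert[vs[later]]
      tgt <- unname(trans[sess_concept[vs[later]]])
      tgt[is.na(tgt)] <- sess_concept[vs[later]][is.na(tgt)]
      # random browsing stays off the alert-drug topic: its pages are
      # reached through drug searches, keeping initiating-term vocabularies
      # on that topic interpretable
      rnd <- sample(c(bg_ids, "c_influenza", "c_oseltamivir"),
                    sum(later), replace = TRUE)
      tgt[!follow] <- rnd[!follow]
      topic_concept[later] <- tgt
    }
    topic <- paste0("T_", topic_concept)

    # repeated same-topic views become subtopic views with prob p_subtopic
    prev_topic <- c(NA_character_, topic[-TV])
    prev_same <- c(FALSE, vs[-1] == vs[-TV]) & !is.na(prev_topic) & topic == prev_topic
    as_sub <- prev_same & runif(TV) < cfg$p_subtopic
    view_action <- rep("topic_view", TV)
    view_action[as_sub] <- "subtopic_view"
    view_payload <- topic
    view_payload[as_sub] <- paste0(topic[as_sub], "/s1")

    # timestamps: search, then views separated by class-conditional
    # log-normal dwell gaps, rounded to whole seconds
    gap_first <- 1 + floor(runif(S, 0, 5))
    gaps <- round(rlnorm(TV, meanlog[vs], cfg$dwell$sdlog))
    gaps[first] <- gap_first
    cs <- cumsum(gaps)
    first_idx <- which(first)
    base <- cs[first_idx] - gaps[first_idx]
    view_ts <- sess_start[vs] + (cs - rep(base, diff(c(first_idx, TV + 1L))))

    # assemble: one search row + V view rows per session, session-major
    n_rows <- S + TV
    row_sess <- rep(seq_len(S), V + 1L)
    is_search_row <- sequence(V + 1L) == 1L
    ts <- as.POSIXct(rep(NA_real_, n_rows), origin = "1970-01-01", tz = cfg$tz)
    ts[is_search_row] <- sess_start
    ts[!is_search_row] <- view_ts
    action <- rep("search", n_rows)
    action[!is_search_row] <- view_action
    payload <- character(n_rows)
    payload[is_search_row] <- query
    payload[!is_search_row] <- view_payload

    # about half the sessions close with a follow-up lookup (a background
    # search), which terminates the final topic view; the rest end on a
    # view, whose dwell is naturally unobservable
    fin <- runif(S) < cfg$p_final_search
    n_fin <- sum(fin)
    if (n_fin > 0) {
      last_view_ts <- view_ts[cumsum(V)]
      ts_fin <- last_view_ts[fin] + round(rlnorm(n_fin, meanlog[fin], cfg$dwell$sdlog))
      ci2 <- sample.int(length(bg_ids), n_fin, replace = TRUE, prob = w)
      term_lists2 <- lapply(meta[bg_ids], `[[`, "terms")
      flat2 <- unlist(term_lists2, use.names = FALSE)
      off2 <- cumsum(c(0L, lengths(term_lists2)[-length(term_lists2)]))
      q_fin <- flat2[off2[ci2] + floor(runif(n_fin) * lengths(term_lists2)[ci2]) + 1L]
      ev <- log_events(c(sess_id[row_sess], sess_id[fin]),
                       c(inst[row_sess], inst[fin]),
                       c(ts, ts_fin),
                       c(action, rep("search", n_fin)),
                       c(payload, q_fin))
    } else {
      ev <- log_events(sess_id[row_sess], inst[row_sess], ts, action, payload)
    }

    search_day <- c(day_idx, match(as.Date(if (n_fin > 0) ts_fin else NULL, tz = cfg$tz), days))
    daily <- tibble::tibble(
      date = days,
      total = tabulate(search_day[!is.na(search_day)], nbins = nd),
      alert_matched = tabulate(day_idx[is_alert], nbins = nd),
      seasonal_matched = tabulate(day_idx[is_seas], nbins = nd)
    )
    truth <- list(
      term_class = term_class,
      daily = daily,
      alert = list(date = cfg$alert$date, onset_date = onset,
                   elevated_duration_days = cfg$alert$elevated_duration_days,
                   effect_multiplier = cfg$alert$effect_multiplier,
                   vocab_base = vocab$base, vocab_broadened = vocab$broadened,
                   dwell_shift = cfg$alert$dwell_shift),
      seasonal = list(peak_month = cfg$seasonal$peak_month),
      category_mix = cfg$category_mix,
      motif = c(paste0("T_", motif_disease), paste0("T_", motif_drug))
    )
    verify_truth(ev, lex, truth)
    list(events = ev, lex = lex, truth = truth)
  })
}

# generation-time consistency check: annotation-level matching must agree
# with the stream bookkeeping for every unique emitted query
verify_truth <- function(ev, lex, truth) {
  queries <- unique(ev$payload[ev$action == "search"])
  if (length(queries) == 0) return(invisible(TRUE))
  terms <- annotate_terms_memo(queries, lex)
  hits_alert <- vapply(terms, function(tt) any(tt %in% alert_terms()), logical(1))
  should <- queries %in% c(truth$alert$vocab_base, truth$alert$vocab_broadened)
  if (!identical(unname(hits_alert), should)) {
    stop("generator inconsistency: annotation-level alert matching disagrees with bookkeeping")
  }
  invisible(TRUE)
}

#' Generate a synthetic media-document stream
#'
#' A baseline Poisson stream of documents mentioning the alert-drug terms,
#' an independent stream of unrelated documents, and an additive mention
#' spike starting at `alert$date + media$spike_day_offset` decaying
#' geometrically (to 5% of its height over `media$decay_days`). Ground
#' truth records the realized matched count per day.
#'
#' @param cfg A [generator_config()].
#' @return A list with `docs` (a media tibble) and `truth`.
#' @export
gen_media <- function(cfg) {
  withr::with_seed(cfg$seed + 2L, {
    days <- seq(cfg$span[1], cfg$span[2], by = "day")
    nd <- length(days)
    spike_start <- cfg$alert$date + cfg$media$spike_day_offset
    d_since <- as.integer(days - spike_start)
    r <- if (cfg$media$decay_days > 0) 0.05^(1 / cfg$media$decay_days) else 0
    extra <- ifelse(d_since >= 0, cfg$media$spike_height * r^d_since, 0)
    n_matched <- rpois(nd, cfg$media$base_rate + extra)
    n_noise <- rpois(nd, cfg$media$noise_rate)

    mk_docs <- function(n_per_day, matched) {
      di <- rep(seq_len(nd), n_per_day)
      n <- length(di)
      if (n == 0) return(NULL)
      ts <- as.POSIXct(days[di], tz = cfg$tz) + floor(runif(n, 0, 86400))
      if (matched) {
        drug <- sample(alert_terms(), n, replace = TRUE)
        title <- paste("safety review of", drug)
        content <- paste("regulators discuss", drug, "and", drug, "again")
      } else {
        title <- sprintf("general news item %d", seq_len(n))
        content <- "unrelated coverage of markets and weather"
      }
      tibble::tibble(title = title, timestamp = ts,
                     url = sprintf("https://example.org/%s/%d",
                                   if (matched) "drug" else "news", seq_len(n)),
                     content = content, day_index = di, matched = matched)
    }
    docs <- dplyr::bind_rows(mk_docs(n_matched, TRUE), mk_docs(n_noise, FALSE))
    if (is.null(docs) || nrow(docs) == 0) {
      docs <- tibble::tibble(title = character(0),
                             timestamp = as.POSIXct(character(0), tz = cfg$tz),
                             url = character(0), content = character(0))
      return(list(docs = docs,
                  truth = list(daily_matched = tibble::tibble(date = days, matched = n_matched),
                               spike_start = spike_start)))
    }
    docs <- docs[order(docs$timestamp), ]
    truth <- list(daily_matched = tibble::tibble(date = days, matched = n_matched),
                  spike_start = spike_start)
    list(docs = docs[, c("title", "timestamp", "url", "content")], truth = truth)
  })
}

#' Write a full set of synthetic fixtures to a directory
#'
#' Emits `log.tsv`, `lexicon.tsv`, `media.jsonl` and `truth.json` (the
#' sidecar ground truth), each embedding the generator seed in a header
#' comment where the format allows one.
#'
#' @param cfg A [generator_config()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
gen_fixtures <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lg <- gen_lexicon(cfg)
  logs <- gen_logs(cfg, lg)
  media <- gen_media(cfg)
  paths <- c(log = file.path(out_dir, "log.tsv"),
             lexicon = file.path(out_dir, "lexicon.tsv"),
             media = file.path(out_dir, "media.jsonl"),
             truth = file.path(out_dir, "truth.json"))
  write_log(logs$events, paths[["log"]])
  prepend_seed_comment(paths[["log"]], cfg$seed)
  write_lexicon(logs$lex, paths[["lexicon"]])
  prepend_seed_comment(paths[["lexicon"]], cfg$seed)
  write_media(media$docs, paths[["media"]])
  truth <- logs$truth
  truth$media = media$truth
  truth$seed <- cfg$seed
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(paths)
}

prepend_seed_comment <- function(path, seed) {
  lines <- readLines(path)
  writeLines(c(sprintf("# generator seed: %d", seed), lines), path, useBytes = TRUE)
  invisible(path)
}
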