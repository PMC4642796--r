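celexa_set <- function() term_set("celexa", c("celexa", "citalopram"))

test_that("daily query counts split matched from total and zero-fill gaps", {
  lex <- fixture_lexicon()
  ts <- as.POSIXct(c("2011-06-01 09:00:00", "2011-06-01 10:00:00",
                     "2011-06-01 11:00:00", "2011-06-03 09:00:00"), tz = "UTC")
  ev <- log_events(paste0("s", 1:4), "i", ts, rep("search", 4),
                   c("celexa", "celexa dose", "other", "citalopram"))
  dc <- daily_query_counts(ev, celexa_set(), lex)
  expect_equal(dc$matched$value, c(2, 0, 1))
  expect_equal(dc$total$value, c(3, 0, 1))
  expect_equal(sum(dc$matched$value), nrow(match_events(ev, celexa_set(), lex)))
  expect_error(daily_query_counts(ev[0, ], celexa_set(), lex), "no search events")
})

test_that("media documents count once per day regardless of mention count", {
  lex <- fixture_lexicon()
  docs <- tibble::tibble(
    title = c("celexa celexa celexa story", "celexa again", "weather"),
    timestamp = as.POSIXct("2011-08-24 12:00:00", tz = "UTC") + c(0, 60, 120),
    url = "u", content = c("more celexa celexa text", "text", "rain"))
  ds <- daily_media_counts(docs, celexa_set(), lex)
  expect_equal(ds$value, 2)
})

test_that("fraction series divides elementwise with a zero-total convention", {
  m <- daily_series(as.Date("2011-01-01"), c(3, 0, 1))
  t <- daily_series(as.Date("2011-01-01"), c(10, 0, 4))
  f <- fraction_series(m, t)
  expect_equal(f$value, c(0.3, 0, 0.25))
  expect_true(all(f$value >= 0 & f$value <= 1))
  t2 <- daily_series(as.Date("2011-01-02"), c(10, 0, 4))
  expect_error(fraction_series(m, t2), "aligned")
  # random-series oracle
  withr::with_seed(8, {
    mv <- rpois(50, 3); tv <- mv + rpois(50, 5)
    f2 <- fraction_series(daily_series(as.Date("2011-01-01"), mv),
                          daily_series(as.Date("2011-01-01"), tv))
    expect_equal(f2$value, ifelse(tv == 0, 0, mv / tv))
  })
})

test_that("the trailing moving average matches a windowed-mean oracle", {
  s <- daily_series(as.Date("2011-01-01"), c(1, 2, 3, 4))
  expect_equal(moving_average(s, 3)$value, c(NA, NA, 2, 3))
  const <- daily_series(as.Date("2011-01-01"), rep(5, 10))
  expect_equal(moving_average(const, 7)$value[7:10], rep(5, 4))
  withr::with_seed(10, {
    x <- rpois(60, 8)
    got <- moving_average(daily_series(as.Date("2011-01-01"), x), 7)$value
    expect_equal(got, oracle_moving_average(x, 7))
  })
  expect_error(moving_average(s, 9), "window longer")
})

test_that("scaling preserves shape and the argmax", {
  withr::with_seed(11, {
    s <- daily_series(as.Date("2011-01-01"), runif(30))
    sc <- scale_series(s, 1e7)
    expect_equal(sc$value, s$value * 1e7)
    expect_equal(which.max(sc$value), which.max(s$value))
    expect_equal(scale_series(s, 1)$value, s$value)
  })
})

test_that("a forced level shift is detected at its first day with its duration", {
  v <- c(rep(10, 39), rep(20, 10), rep(10, 31)) + rep(c(-1, 1), 40)
  s <- daily_series(as.Date("2011-01-01"), v)
  sig <- detect_signal(s, baseline = c(as.Date("2011-01-01"), as.Date("2011-02-08")),
                       k = 3, min_run = 3)
  expect_equal(sig$onset_date, as.Date("2011-01-01") + 39)
  expect_equal(sig$elevated_duration_days, 10L)
  expect_true(sig$peak_date >= sig$onset_date)
  # a flat-noise series yields no onset
  flat <- daily_series(as.Date("2011-01-01"), rep(c(9, 11), 20))
  expect_true(is.na(detect_signal(flat)$onset_date))
  # degenerate baseline falls back to mean + 1
  dg <- detect_signal(daily_series(as.Date("2011-01-01"), c(rep(5, 20), rep(7, 5), rep(5, 5))),
                      baseline = c(as.Date("2011-01-01"), as.Date("2011-01-20")))
  expect_true(dg$degenerate)
  expect_equal(dg$threshold, 6)
  expect_equal(dg$elevated_duration_days, 5L)
})

test_that("signal detection is translation-equivariant", {
  withr::with_seed(13, {
    base <- rpois(120, 10)
    for (shift in c(0, 7, 15)) {
      v <- base
      v[(61 + shift):(75 + shift)] <- v[(61 + shift):(75 + shift)] + 40
      sig <- detect_signal(daily_series(as.Date("2011-01-01"), v),
                           baseline = c(as.Date("2011-01-01"), as.Date("2011-02-25")))
      expect_equal(sig$onset_date, as.Date("2011-01-01") + 60 + shift)
    }
  })
})

test_that("stream comparison reports lag and persistence", {
  sigA <- structure(list(onset_date = as.Date("2011-09-03"), elevated_duration_days = 60L),
                    class = "signal")
  sigB <- structure(list(onset_date = as.Date("2011-08-24"), elevated_duration_days = 12L),
                    class = "signal")
  cmp <- compare_streams(sigA, sigB)
  expect_equal(cmp$onset_lag_days, 10L)
  expect_equal(cmp$duration_ratio, 5)
  expect_equal(compare_streams(sigA, sigA)$onset_lag_days, 0L)
  none <- structure(list(onset_date = as.Date(NA)), class = "signal")
  expect_error(compare_streams(none, sigB), "log stream")
  expect_error(compare_streams(sigA, none), "media stream")
})

test_that("the pre/post report counts terms and specificity by hand-checkable windows", {
  lex <- fixture_lexicon()
  base <- as.POSIXct("2011-08-20 09:00:00", tz = "UTC")
  queries <- c("celexa", "citalopram dose",             # 2 pre-alert sessions
               "celexa", "celexa long qt", "citalopram heart")  # 3 post
  day_off <- c(0, 1, 9, 10, 11) * 86400
  dur <- c(400, 300, 70, 60, 50)
  mk <- function(i) {
    log_events(rep(paste0("s", i), 3), "i",
               base + day_off[i] + c(0, 10, 10 + dur[i]),
               c("search", "topic_view", "search"),
               c(queries[i], "T_cit", "done"))
  }
  ev <- do.call(rbind, lapply(1:5, mk))
  rep_ <- pre_post_report(ev, as.Date("2011-08-24"),
                          term_set("drug", c("celexa", "citalopram")),
                          term_set("spec", c("long qt", "heart", "rhythm")),
                          lex, boundary = 143.79)
  expect_equal(rep_$pre_unique_terms, 2L)   # "celexa", "citalopram dose"
  expect_equal(rep_$post_unique_terms, 3L)  # "celexa", "celexa long qt", "citalopram heart"
  expect_equal(rep_$specificity_pre, 0L)
  expect_equal(rep_$specificity_post, 2L)
  expect_error(
    pre_post_report(ev, as.Date("2011-08-01"),
                    term_set("drug", c("celexa", "citalopram")),
                    term_set("spec", "long qt"), lex),
    "outside the log span|pre or post")
})

test_that("planted post-alert broadening and dwell drop are recovered across seeds", {
  hits <- 0L
  for (seed in 1:20) {
    cfg <- generator_config(
      seed = seed, span = as.Date(c("2011-06-01", "2011-11-30")),
      sessions_per_day = 30,
      alert = list(lag_days = 5, elevated_duration_days = 60, dwell_shift = -0.3))
    g <- gen_logs(cfg)
    rep_ <- pre_post_report(g$events, cfg$alert$date,
                            term_set("drug", g$truth$alert$vocab_base),
                            term_set("spec", c("long qt", "heart", "rhythm")),
                            g$lex)
    drug_dw_pre <- rep_$pre_mean_dwell
    ok <- rep_$post_unique_terms > rep_$pre_unique_terms &&
      rep_$post_mean_dwell < drug_dw_pre
    hits <- hits + ok
  }
  expect_gte(hits, 18L)
})

test_that("planted lag between media spike and log response is recovered", {
  cfg <- generator_config(seed = 99, span = as.Date(c("2011-06-01", "2011-12-31")),
                          sessions_per_day = 60)
  g <- gen_logs(cfg)
  m <- gen_media(cfg)
  dc <- daily_query_counts(g$events, term_set("celexa", g$truth$alert$vocab_base),
                           g$lex, span = cfg$span)
  baseline <- c(cfg$span[1], cfg$alert$date - 7)
  log_sig <- detect_signal(dc$matched, baseline = baseline)
  med_sig <- detect_signal(daily_media_counts(m$docs, term_set("celexa", g$truth$alert$vocab_base),
                                              g$lex, span = cfg$span),
                           baseline = baseline)
  cmp <- compare_streams(log_sig, med_sig)
  planted_lag <- as.integer(g$truth$alert$onset_date - m$truth$spike_start)
  expect_lte(abs(cmp$onset_lag_days - planted_lag), 2L)
  expect_gt(cmp$duration_ratio, 1)
})
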