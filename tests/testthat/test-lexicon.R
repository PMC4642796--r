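test_that("normalization lowercases, strips punctuation and is idempotent", {
  expect_equal(normalize_text("Celexa  (citalopram)"), "celexa citalopram")
  expect_equal(normalize_text(""), "")
  expect_equal(normalize_text("  HTN--stage 2!  "), "htn stage 2")
  withr::with_seed(7, {
    raw <- vapply(1:1000, function(i) {
      paste(sample(c(letters, LETTERS, 0:9, "-", "(", ")", ".", " ", "é", "ﬁ"),
                   sample(1:30, 1), replace = TRUE), collapse = "")
    }, "")
    once <- normalize_text(raw)
    expect_identical(normalize_text(once), once)
  })
})

test_that("a three-line fixture loads into one concept with two synonyms", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#concept_id\tterm\tcategory\tparent_concept_id",
               "c_cit\tCelexa\tdrug\t",
               "c_cit\tcitalopram\tdrug\t"), f)
  lex <- load_lexicon(f)
  expect_length(lex$concept_terms, 1)
  expect_setequal(lex$concept_terms$c_cit, c("celexa", "citalopram"))
  expect_equal(unname(lex$concept_category[["c_cit"]]), "drug")
})

test_that("contradictory categories and hierarchy cycles are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\tfoo\tdrug\t", "c1\tbar\tdevice\t"), f)
  expect_error(load_lexicon(f), "contradictory category.*c1")
  writeLines(c("c1\tfoo\tdrug\tc2", "c2\tbar\tdrug\tc1"), f)
  expect_error(load_lexicon(f), "cycle")
})

test_that("load-dump-load is the identity on random lexicons", {
  for (seed in c(11, 12, 13)) {
    df <- random_lexicon_df(200, seed)
    lex1 <- lexicon_from_df(df)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_lexicon(lex1, f)
    lex2 <- load_lexicon(f)
    expect_equal(lapply(lex1$concept_terms, sort), lapply(lex2$concept_terms, sort))
    expect_equal(lex1$concept_category[sort(names(lex1$concept_category))],
                 lex2$concept_category[sort(names(lex2$concept_category))])
  }
})

test_that("annotation picks lexicon terms at token boundaries", {
  lex <- fixture_lexicon()
  a <- annotate_query("tamiflu dose", lex)
  expect_equal(a$matches$term, "tamiflu")
  expect_equal(a$matches$start, 1L)
  expect_equal(a$matches$end, 7L)
  expect_equal(a$matches$concepts[[1]], "c_oselt")

  # maps the coded phrase onto the hypertensive-disease concept
  b <- annotate_query("Essential Hypertension NOS", lex)
  expect_equal(b$matches$term, "essential hypertension nos")
  expect_equal(b$matches$concepts[[1]], "c_htn")
})

test_that("the longest term wins when terms nest", {
  lex <- fixture_lexicon()
  a <- annotate_query("diabetes insipidus workup", lex)
  expect_equal(a$matches$term, "diabetes insipidus")
  expect_equal(a$matches$concepts[[1]], "c_di")
  # but the shorter term still matches alone
  expect_equal(annotate_query("diabetes workup", lex)$matches$term, "diabetes")
})

test_that("annotation equals the brute-force maximal-match oracle on random queries", {
  df <- random_lexicon_df(40, seed = 21)
  lex <- lexicon_from_df(df)
  all_terms <- names(lex$term_to_concepts)
  pool <- unique(unlist(strsplit(all_terms, " ")))
  withr::with_seed(22, {
    for (i in 1:500) {
      q <- paste(sample(c(pool, "zzz", "qqq"), sample(1:6, 1), replace = TRUE),
                 collapse = " ")
      got <- annotate_query(q, lex)$matches$term
      expect_identical(got, oracle_annotate_terms(normalize_text(q), all_terms),
                       label = paste("query:", q))
    }
  })
})

test_that("annotation matches never overlap and align to token boundaries", {
  df <- random_lexicon_df(30, seed = 31)
  lex <- lexicon_from_df(df)
  pool <- unique(unlist(strsplit(names(lex$term_to_concepts), " ")))
  withr::with_seed(32, {
    for (i in 1:100) {
      q <- paste(sample(pool, sample(2:8, 1), replace = TRUE), collapse = " ")
      a <- annotate_query(q, lex)
      m <- a$matches
      if (nrow(m) > 1) expect_true(all(m$start[-1] > m$end[-nrow(m)]))
      for (j in seq_len(nrow(m))) {
        expect_equal(substr(a$normalized, m$start[j], m$end[j]), m$term[j])
        # boundary-aligned: neighbours are string edges or spaces
        before <- if (m$start[j] == 1) " " else substr(a$normalized, m$start[j] - 1, m$start[j] - 1)
        after <- substr(paste0(a$normalized, " "), m$end[j] + 1, m$end[j] + 1)
        expect_equal(c(before, after), c(" ", " "))
      }
    }
  })
})

test_that("one-hop expansion returns the seed's concept synonyms minus exclusions", {
  lex <- fixture_lexicon()
  ts <- expand_term_set("essential hypertension nos", lex, name = "htn")
  expect_setequal(ts$terms, c("essential hypertension nos", "hypertensive disease",
                              "high blood pressure"))
  ts2 <- expand_term_set("essential hypertension nos", lex,
                         exclusions = "high blood pressure", name = "htn")
  expect_setequal(ts2$terms, c("essential hypertension nos", "hypertensive disease"))
  # unknown seed survives alone
  expect_setequal(expand_term_set("zzzz", lex)$terms, "zzzz")
  # empty after exclusion is an error
  expect_error(expand_term_set("zzzz", lex, exclusions = "zzzz"), "empty")
})

test_that("expansion equals the brute-force one-hop closure on random lexicons", {
  for (seed in 41:60) {
    df <- random_lexicon_df(25, seed)
    lex <- lexicon_from_df(df)
    withr::with_seed(seed + 1000, {
      seeds <- sample(df$term, sample(1:3, 1))
      excl <- sample(df$term, 1)
    })
    got <- tryCatch(expand_term_set(seeds, lex, exclusions = excl)$terms,
                    error = function(e) character(0))
    want <- oracle_expand(unique(normalize_text(seeds)), df, normalize_text(excl))
    expect_setequal(got, want)
  }
})

test_that("match_events recovers exactly the planted matching searches", {
  lex <- fixture_lexicon()
  set <- term_set("flu", c("influenza", "flu"))
  withr::with_seed(5, {
    n <- 2000
    planted <- sort(sample(n, 150))
    payload <- paste0("bg", seq_len(n))
    payload[planted] <- sample(c("influenza", "flu treatment", "flu"), 150, replace = TRUE)
    ev <- log_events(paste0("s", seq_len(n)), "i",
                     as.POSIXct("2011-01-01", tz = "UTC") + seq_len(n),
                     rep("search", n), payload)
  })
  hit <- match_events(ev, set, lex)
  expect_equal(hit$session_id, paste0("s", planted))
})

test_that("monthly volumes zero-fill the span and sum to the match count", {
  lex <- fixture_lexicon()
  set <- term_set("cit", "celexa")
  ts <- as.POSIXct(c("2011-01-05 10:00:00", "2011-01-20 10:00:00",
                     "2011-02-10 10:00:00", "2011-04-01 10:00:00"), tz = "UTC")
  ev <- log_events(paste0("s", 1:4), "i", ts, rep("search", 4),
                   c("celexa", "celexa dose", "celexa", "unrelated"))
  mv <- monthly_volume(ev, set, lex)
  expect_equal(mv$count, c(2L, 1L, 0L, 0L))  # Jan..Apr, zero-filled
  expect_equal(sum(mv$count), nrow(match_events(ev, set, lex)))
})

test_that("category proportions are per-system, non-exclusive, and sum to 1", {
  lex <- fixture_lexicon()
  sys_a <- term_set("a", c("influenza", "diabetes", "heart", "tamiflu"))
  sys_b <- term_set("b", c("influenza"))
  ev <- log_events(paste0("s", 1:4), "i",
                   as.POSIXct("2011-01-01", tz = "UTC") + 1:4,
                   rep("search", 4),
                   c("influenza", "diabetes", "heart", "tamiflu"))
  cd <- category_distribution(ev, list(sys_a, sys_b), lex)
  a <- cd[cd$system == "a", ]
  expect_equal(a$proportion[a$category == "disease_symptom"], 0.75)
  expect_equal(a$proportion[a$category == "drug"], 0.25)
  expect_equal(sum(a$proportion), 1)
  # the influenza search also counts for system b
  b <- cd[cd$system == "b", ]
  expect_equal(b$proportion[b$category == "disease_symptom"], 1)
})

test_that("burden_join flags top-ranked conditions per axis", {
  withr::with_seed(9, {
    qv <- tibble::tibble(condition = paste0("c", 1:12), queries = sample(100, 12))
    bt <- tibble::tibble(condition = paste0("c", c(1:11, 13)),
                         cost = sample(1000, 12), discharges = sample(500, 12))
  })
  j <- burden_join(qv, bt, top_n = 3)
  expect_equal(nrow(j), 11)  # c12 and c13 dropped
  expect_setequal(j$condition[j$top_cost], j$condition[order(-j$cost)][1:3])
  expect_setequal(j$condition[j$top_queries], j$condition[order(-j$queries)][1:3])
  # single condition: all flags true
  j1 <- burden_join(qv[1, ], bt[1, ])
  expect_true(all(j1$top_cost, j1$top_discharges, j1$top_queries))
  expect_error(burden_join(qv[12, ], bt[12, ]), "no conditions in common")
})
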