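#' Normalize free-text for annotation
#'
#' Applies the normalization used throughout the package before any term
#' matching: Unicode NFKC, lower case, punctuation mapped to spaces,
#' whitespace collapsed and trimmed. Idempotent.
#'
#' @param text Character vector.
#' @return Character vector of the same length.
#' @export
normalize_text <- function(text) {
  x <- stringi::stri_trans_nfkc(as.character(text))
  x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_replace_all_regex(x, "[^\\p{L}\\p{N}\\s]", " ")
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

#' Construct a lexicon
#'
#' A lexicon maps normalized terms to biomedical concepts (many-to-many,
#' synonymy), concepts to one of four semantic categories (diseases and
#' symptoms, drugs, devices, procedures; or none), and holds an acyclic
#' parent-child concept hierarchy.
#'
#' @param term_concepts A tibble/data.frame with columns `term`,
#'   `concept_id` (one row per term-concept pair).
#' @param concept_category Named character vector, concept id -> category.
#' @param hierarchy A tibble with columns `parent`, `child` (may be empty).
#' @return A list of class `lexicon` with components `term_to_concepts`,
#'   `concept_terms`, `concept_category`, `hierarchy`, `max_term_tokens`.
#' @export
lexicon <- function(term_concepts, concept_category, hierarchy = NULL) {
  term_concepts <- tibble::as_tibble(term_concepts)
  term_concepts$term <- normalize_text(term_concepts$term)
  term_concepts <- dplyr::distinct(term_concepts, .data$term, .data$concept_id)
  if (any(!nzchar(term_concepts$term))) stop("lexicon contains an empty term after normalization")
  bad_cat <- setdiff(unique(concept_category), lexicon_categories())
  if (length(bad_cat)) stop("unknown semantic category: ", paste(bad_cat, collapse = ", "))
  missing_cat <- setdiff(term_concepts$concept_id, names(concept_category))
  if (length(missing_cat)) {
    concept_category <- c(concept_category,
                          stats::setNames(rep("none", length(missing_cat)), missing_cat))
  }
  if (is.null(hierarchy)) hierarchy <- tibble::tibble(parent = character(0), child = character(0))
  hierarchy <- tibble::as_tibble(hierarchy)
  assert_acyclic(hierarchy)
  term_to_concepts <- split(term_concepts$concept_id, term_concepts$term)
  concept_terms <- split(term_concepts$term, term_concepts$concept_id)
  structure(
    list(term_to_concepts = term_to_concepts,
         concept_terms = concept_terms,
         concept_category = concept_category,
         hierarchy = hierarchy,
         max_term_tokens = max(1L, stringi::stri_count_fixed(names(term_to_concepts), " ") + 1L)),
    class = "lexicon"
  )
}

#' Semantic categories a concept may carry
#' @export
lexicon_categories <- function() {
  c("disease_symptom", "drug", "device", "procedure", "none")
}

assert_acyclic <- function(hierarchy) {
  # Kahn's algorithm; leftover edges imply a cycle.
  edges <- hierarchy
  repeat {
    if (nrow(edges) == 0) return(invisible(TRUE))
    roots <- setdiff(edges$parent, edges$child)
    if (length(roots) == 0) stop("cycle detected in concept hierarchy")
    edges <- edges[!edges$parent %in% roots, ]
  }
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon: %d terms, %d concepts, %d hierarchy edges>\n",
              length(x$term_to_concepts), length(x$concept_terms), nrow(x$hierarchy)))
  invisible(x)
}

#' Read a lexicon from its TSV format
#'
#' Expected columns: `concept_id`, `term`, `category`,
#' `parent_concept_id` (empty string when the concept has no parent). A
#' `#`-prefixed header line is skipped. Terms are normalized on load. A
#' concept assigned two different categories, or a cyclic hierarchy, is an
#' error.
#'
#' @param path Path to the lexicon TSV.
#' @return A [lexicon()].
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) stop("empty lexicon file: ", path)
  parts <- split_fields(lines, "\t")
  if (any(lengths(parts) != 4)) {
    stop("malformed lexicon row (expected 4 tab-separated columns) at line ",
         which(lengths(parts) != 4)[1])
  }
  mat <- do.call(rbind, parts)
  df <- tibble::tibble(concept_id = mat[, 1], term = mat[, 2],
                       category = mat[, 3], parent = mat[, 4])
  cat_by_concept <- dplyr::distinct(df, .data$concept_id, .data$category)
  dup <- cat_by_concept$concept_id[duplicated(cat_by_concept$concept_id)]
  if (length(dup)) {
    stop("contradictory category assignment for concept(s): ",
         paste(unique(dup), collapse = ", "))
  }
  concept_category <- stats::setNames(cat_by_concept$category, cat_by_concept$concept_id)
  with_parent <- df[nzchar(df$parent), ]
  hier <- dplyr::distinct(tibble::tibble(parent = with_parent$parent,
                                         child = with_parent$concept_id))
  lexicon(df[, c("term", "concept_id")], concept_category, hier)
}

#' Write a lexicon to its TSV format
#'
#' Inverse of [load_lexicon()] up to row order (rows are sorted by concept
#' then term, so load-dump-load is the identity).
#'
#' @param lex A [lexicon()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "lexicon"))
  parent_of <- stats::setNames(lex$hierarchy$parent, lex$hierarchy$child)
  rows <- purrr::imap(lex$concept_terms, function(terms, cid) {
    tibble::tibble(concept_id = cid, term = sort(terms),
                   category = unname(lex$concept_category[[cid]]),
                   parent = if (cid %in% names(parent_of)) parent_of[[cid]] else "")
  })
  df <- dplyr::arrange(dplyr::bind_rows(rows), .data$concept_id, .data$term)
  lines <- paste(df$concept_id, df$term, df$category, df$parent, sep = "\t")
  writeLines(c("#concept_id\tterm\tcategory\tparent_concept_id", lines), path,
             useBytes = TRUE)
  invisible(path)
}

#' Annotate a free-text query against a lexicon
#'
#' Greedy longest-match-first, left-to-right matching over the normalized
#' query. Matches align to token boundaries, never overlap, and each carries
#' every concept the matched term maps to. Offsets are 1-based inclusive
#' character positions into the normalized string.
#'
#' @param query A single query string.
#' @param lex A [lexicon()].
#' @return A list of class `annotated_query` with `raw`, `normalized`, and
#'   a `matches` tibble (`start`, `end`, `term`, `concepts` list-column).
#' @export
annotate_query <- function(query, lex) {
  stopifnot(inherits(lex, "lexicon"), length(query) == 1)
  norm <- normalize_text(query)
  matches <- tibble::tibble(start = integer(0), end = integer(0),
                            term = character(0), concepts = list())
  if (nzchar(norm)) {
    toks <- strsplit(norm, " ", fixed = TRUE)[[1]]
    n <- length(toks)
    # token start offsets in the normalized string (single spaces guaranteed)
    widths <- nchar(toks)
    starts <- cumsum(c(1L, widths[-n] + 1L))
    ends <- starts + widths - 1L
    out_start <- integer(0); out_end <- integer(0)
    out_term <- character(0); out_concepts <- list()
    i <- 1L
    while (i <= n) {
      matched_len <- 0L
      for (len in seq(min(lex$max_term_tokens, n - i + 1L), 1L)) {
        cand <- paste(toks[i:(i + len - 1L)], collapse = " ")
        cids <- lex$term_to_concepts[[cand]]
        if (!is.null(cids)) {
          out_start <- c(out_start, starts[i])
          out_end <- c(out_end, ends[i + len - 1L])
          out_term <- c(out_term, cand)
          out_concepts <- c(out_concepts, list(cids))
          matched_len <- len
          break
        }
      }
      i <- i + max(1L, matched_len)
    }
    matches <- tibble::tibble(start = out_start, end = out_end,
                              term = out_term, concepts = out_concepts)
  }
  structure(list(raw = query, normalized = norm, matches = matches),
            class = "annotated_query")
}

# Matched terms for each of a vector of queries, memoized over unique raw
# queries (logs repeat the same query strings heavily).
annotate_terms_memo <- function(queries, lex) {
  uq <- unique(queries)
  hit <- lapply(normalize_text(uq), function(q) annotate_query(q, lex)$matches$term)
  hit[match(queries, uq)]
}

# Does each query's annotation contain a term of the set? Computed once per
# unique raw query.
query_matches <- function(queries, set, lex) {
  uq <- unique(queries)
  hit_u <- vapply(normalize_text(uq), function(q) {
    any(annotate_query(q, lex)$matches$term %in% set$terms)
  }, logical(1), USE.NAMES = FALSE)
  hit_u[match(queries, uq)]
}

#' Construct a term set
#'
#' A curated set of synonym strings representing a clinical entity (a body
#' system, a condition-code group, a drug). Exclusions record terms removed
#' by review; they are disjoint from the active terms.
#'
#' @param name Label.
#' @param terms Character vector of terms (normalized on construction).
#' @param exclusions Terms removed by review.
#' @return A list of class `term_set`.
#' @export
term_set <- function(name, terms, exclusions = character(0)) {
  terms <- unique(normalize_text(terms))
  exclusions <- unique(normalize_text(exclusions))
  terms <- setdiff(terms, exclusions)
  if (length(terms) == 0) stop("term set '", name, "' is empty after exclusions")
  structure(list(name = name, terms = terms, exclusions = exclusions),
            class = "term_set")
}

#' @export
print.term_set <- function(x, ...) {
  cat(sprintf("<term_set '%s': %d terms, %d exclusions>\n",
              x$name, length(x$terms), length(x$exclusions)))
  invisible(x)
}

#' Expand seed terms into a term set via the lexicon
#'
#' One expansion hop: every seed term is looked up in the lexicon; the full
#' synonym sets of all concepts it maps to are unioned with the seeds, then
#' the exclusions (mechanized manual review) are removed. Seeds unknown to
#' the lexicon survive unchanged. With `transitive = TRUE` the synonym sets
#' of hierarchical descendants of the mapped concepts are also pulled in
#' (off by default: deeper closure tends to over-broaden sets).
#'
#' @param seed_terms Character vector of seed terms.
#' @param lex A [lexicon()].
#' @param exclusions Terms to remove after expansion.
#' @param name Name for the resulting set.
#' @param transitive Include descendant concepts' terms as well.
#' @return A [term_set()].
#' @export
expand_term_set <- function(seed_terms, lex, exclusions = character(0),
                            name = "expanded", transitive = FALSE) {
  stopifnot(inherits(lex, "lexicon"))
  seeds <- unique(normalize_text(seed_terms))
  cids <- unique(unlist(lex$term_to_concepts[intersect(seeds, names(lex$term_to_concepts))]))
  if (transitive && length(cids)) {
    frontier <- cids
    repeat {
      kids <- unique(lex$hierarchy$child[lex$hierarchy$parent %in% frontier])
      kids <- setdiff(kids, cids)
      if (length(kids) == 0) break
      cids <- c(cids, kids)
      frontier <- kids
    }
  }
  expanded <- unique(c(seeds, unlist(lex$concept_terms[intersect(cids, names(lex$concept_terms))])))
  term_set(name, expanded, exclusions)
}

#' Read a term-set definition from YAML
#'
#' Fields: `name`, `seeds`, optional `exclusions`, optional `expand` flag.
#' When `expand` is true a lexicon must be supplied and the seeds are
#' expanded with [expand_term_set()].
#'
#' @param path YAML file path.
#' @param lex A [lexicon()], required when the file requests expansion.
#' @return A [term_set()].
#' @export
load_term_set <- function(path, lex = NULL) {
  y <- yaml::read_yaml(path)
  if (is.null(y$name) || is.null(y$seeds)) stop("term-set YAML needs 'name' and 'seeds'")
  exclusions <- y$exclusions %||% character(0)
  if (isTRUE(y$expand)) {
    if (is.null(lex)) stop("term set '", y$name, "' requests expansion; supply a lexicon")
    expand_term_set(unlist(y$seeds), lex, unlist(exclusions), name = y$name)
  } else {
    term_set(y$name, unlist(y$seeds), unlist(exclusions))
  }
}

#' Select search events matching a term set
#'
#' A search event matches when its annotation (greedy longest-match against
#' the lexicon) contains at least one term of the set, so multiword terms
#' respect token boundaries.
#'
#' @param events A `log_events` tibble.
#' @param set A [term_set()].
#' @param lex A [lexicon()].
#' @return The matching subset of the search events, input order preserved.
#' @export
match_events <- function(events, set, lex) {
  stopifnot(inherits(set, "term_set"), inherits(lex, "lexicon"))
  searches <- events[events$action == "search", ]
  if (nrow(searches) == 0) return(searches)
  searches[query_matches(searches$payload, set, lex), ]
}

#' Monthly matched-query volumes
#'
#' Counts term-set-matched search events per calendar month; months with no
#' matches appear with count 0 across the log's span.
#'
#' @inheritParams match_events
#' @return A tibble with columns `year`, `month`, `count`.
#' @export
monthly_volume <- function(events, set, lex) {
  searches <- events[events$action == "search", ]
  if (nrow(searches) == 0) {
    return(tibble::tibble(year = integer(0), month = integer(0), count = integer(0)))
  }
  tz <- attr(searches$timestamp, "tzone") %||% "UTC"
  span_dates <- as.Date(range(searches$timestamp), tz = tz)
  months <- seq(as.Date(format(span_dates[1], "%Y-%m-01")),
                as.Date(format(span_dates[2], "%Y-%m-01")), by = "month")
  matched <- match_events(events, set, lex)
  key <- format(matched$timestamp, "%Y-%m", tz = tz)
  counts <- table(key)
  all_keys <- format(months, "%Y-%m")
  n <- as.integer(counts[all_keys])
  n[is.na(n)] <- 0L
  tibble::tibble(year = as.integer(substr(all_keys, 1, 4)),
                 month = as.integer(substr(all_keys, 6, 7)),
                 count = n)
}

#' Category distribution of matched searches per body system
#'
#' For each system term set, takes every search event matching the set and
#' tallies the semantic categories of the concepts behind the matched set
#' terms (each matched term counted once per category among its concepts,
#' `none` ignored). Systems are not exclusive: a search matching two
#' systems contributes to both. Proportions sum to 1 for any system with at
#' least one categorized match.
#'
#' @param events A `log_events` tibble.
#' @param system_term_sets A list of [term_set()]s.
#' @param lex A [lexicon()].
#' @return A tibble with columns `system`, `category`, `proportion`.
#' @export
category_distribution <- function(events, system_term_sets, lex) {
  cats <- setdiff(lexicon_categories(), "none")
  searches <- events[events$action == "search", ]
  terms_per_query <- if (nrow(searches)) annotate_terms_memo(searches$payload, lex) else list()
  rows <- purrr::map(system_term_sets, function(set) {
    counts <- stats::setNames(rep(0, length(cats)), cats)
    for (tt in terms_per_query) {
      in_set <- intersect(tt, set$terms)
      for (term in in_set) {
        cc <- unique(unname(lex$concept_category[lex$term_to_concepts[[term]]]))
        cc <- setdiff(cc, "none")
        counts[cc] <- counts[cc] + 1
      }
    }
    tot <- sum(counts)
    tibble::tibble(system = set$name, category = cats,
                   proportion = if (tot > 0) unname(counts) / tot else rep(NA_real_, length(cats)))
  })
  dplyr::bind_rows(rows)
}

#' Join query volumes with a disease-burden table
#'
#' Inner join of per-condition query volumes with a burden table (aggregate
#' cost and discharge volume per condition), flagging top-10 membership on
#' each axis. Conditions missing from either side are dropped.
#'
#' @param query_volumes Tibble with columns `condition`, `queries`.
#' @param burden_table Tibble with columns `condition`, `cost`, `discharges`.
#' @param top_n Rank cutoff for the flags (default 10).
#' @return A tibble with the joined columns plus `top_cost`,
#'   `top_discharges`, `top_queries` logical flags.
#' @export
burden_join <- function(query_volumes, burden_table, top_n = 10) {
  joined <- dplyr::inner_join(tibble::as_tibble(query_volumes),
                              tibble::as_tibble(burden_table), by = "condition")
  if (nrow(joined) == 0) stop("no conditions in common between query volumes and burden table")
  joined$top_cost <- rank(-joined$cost, ties.method = "min") <= top_n
  joined$top_discharges <- rank(-joined$discharges, ties.method = "min") <= top_n
  joined$top_queries <- rank(-joined$queries, ties.method = "min") <= top_n
  joined
}
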