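#' Log file dialect
#'
#' Describes the physical format of a usage-log file: column order,
#' delimiter, timestamp format and the timezone in which timestamps are to
#' be interpreted. One dialect (and hence one timezone) applies to a whole
#' file; daily aggregation downstream uses that timezone's calendar dates.
#'
#' @param delimiter Field delimiter, default tab.
#' @param timestamp_format A [strptime()] format string.
#' @param tz Timezone name applied to every timestamp in the file.
#' @param columns Column order; a permutation of the five canonical names.
#' @param header Logical; whether files carry a `#`-prefixed header line.
#' @return A list of class `log_dialect`.
#' @export
log_dialect <- function(delimiter = "\t",
                        timestamp_format = "%Y-%m-%dT%H:%M:%S",
                        tz = "UTC",
                        columns = c("session_id", "institution_id",
                                    "timestamp", "action", "payload"),
                        header = TRUE) {
  canonical <- c("session_id", "institution_id", "timestamp", "action", "payload")
  if (!setequal(columns, canonical)) {
    stop("`columns` must be a permutation of: ", paste(canonical, collapse = ", "))
  }
  structure(
    list(delimiter = delimiter, timestamp_format = timestamp_format,
         tz = tz, columns = columns, header = header),
    class = "log_dialect"
  )
}

#' Event actions recognised in a usage log
#' @export
log_actions <- function() c("search", "topic_view", "subtopic_view")

#' Construct a validated log-event table
#'
#' One row per timestamped user action (a free-text search, a topic view,
#' or a subtopic view within a topic page). The payload holds the query
#' string for searches and a topic identifier otherwise; subtopic views
#' carry `parent_topic/subtopic` identifiers.
#'
#' @param session_id,institution_id Character vectors.
#' @param timestamp A `POSIXct` vector.
#' @param action Character vector; each element one of [log_actions()].
#' @param payload Non-empty character vector.
#' @return A tibble with class `log_events`.
#' @export
log_events <- function(session_id, institution_id, timestamp, action, payload) {
  ev <- tibble::tibble(
    session_id = as.character(session_id),
    institution_id = as.character(institution_id),
    timestamp = timestamp,
    action = as.character(action),
    payload = as.character(payload)
  )
  validate_log_events(ev)
}

validate_log_events <- function(ev) {
  stopifnot(inherits(ev$timestamp, "POSIXct"))
  bad_action <- !ev$action %in% log_actions()
  if (any(bad_action)) {
    stop("unknown action(s): ", paste(unique(ev$action[bad_action]), collapse = ", "))
  }
  if (any(is.na(ev$payload) | ev$payload == "")) {
    stop("empty payload in event row(s): ",
         paste(utils::head(which(is.na(ev$payload) | ev$payload == ""), 5), collapse = ", "))
  }
  if (any(is.na(ev$timestamp))) {
    stop("missing timestamp in event row(s): ",
         paste(utils::head(which(is.na(ev$timestamp)), 5), collapse = ", "))
  }
  class(ev) <- c("log_events", class(ev))
  ev
}

# Escape/unescape so delimiter and newline characters survive a round trip.
escape_field <- function(x, delimiter) {
  x <- stringr::str_replace_all(x, stringr::fixed("\\"), "\\\\")
  x <- stringr::str_replace_all(x, stringr::fixed("\t"), "\\t")
  x <- stringr::str_replace_all(x, stringr::fixed("\n"), "\\n")
  if (delimiter != "\t") x <- stringr::str_replace_all(x, stringr::fixed(delimiter), paste0("\\", delimiter))
  x
}

unescape_field <- function(x, delimiter) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[[i]], "", fixed = TRUE)[[1]]
    buf <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      if (chars[[j]] == "\\" && j < length(chars)) {
        nxt <- chars[[j + 1L]]
        buf <- c(buf, switch(nxt, t = "\t", n = "\n", nxt))
        j <- j + 2L
      } else {
        buf <- c(buf, chars[[j]])
        j <- j + 1L
      }
    }
    out[[i]] <- paste(buf, collapse = "")
  }
  out
}

# strsplit drops trailing empty fields; a sentinel keeps them
split_fields <- function(lines, delimiter) {
  parts <- strsplit(paste0(lines, "\x01"), delimiter, fixed = TRUE)
  lapply(parts, function(p) {
    p[length(p)] <- sub("\x01$", "", p[length(p)])
    p
  })
}

#' Read a usage log
#'
#' Reads a delimited log file into a validated event table, preserving file
#' order. Malformed rows (wrong column count, unparseable timestamp, unknown
#' action, empty payload) abort with the offending line number.
#'
#' @param path Path to the log file.
#' @param dialect A [log_dialect()].
#' @return A `log_events` tibble.
#' @export
read_log <- function(path, dialect = log_dialect()) {
  if (!file.exists(path)) stop("log file not found: ", path)
  parsed <- parse_log_lines(readLines(path, encoding = "UTF-8"), dialect)
  if (nrow(parsed$problems) > 0) {
    p <- parsed$problems[1, ]
    stop(sprintf("malformed log row at line %d: %s", p$line, p$problem))
  }
  parsed$events
}

# Shared parser: returns both well-formed events and per-line diagnostics.
parse_log_lines <- function(lines, dialect) {
  problems <- tibble::tibble(line = integer(0), problem = character(0))
  is_data <- !startsWith(lines, "#") & nzchar(lines)
  data_lines <- lines[is_data]
  line_no <- which(is_data)
  if (length(data_lines) == 0) {
    ev <- log_events(character(0), character(0),
                     as.POSIXct(character(0), tz = dialect$tz),
                     character(0), character(0))
    return(list(events = ev, problems = problems))
  }
  parts <- split_fields(data_lines, dialect$delimiter)
  ncols <- lengths(parts)
  bad_ncol <- ncols != length(dialect$columns)
  if (any(bad_ncol)) {
    problems <- dplyr::bind_rows(problems, tibble::tibble(
      line = line_no[bad_ncol],
      problem = sprintf("expected %d columns, found %d",
                        length(dialect$columns), ncols[bad_ncol])
    ))
  }
  keep <- !bad_ncol
  mat <- do.call(rbind, parts[keep])
  if (is.null(mat)) mat <- matrix(character(0), ncol = length(dialect$columns))
  colnames(mat) <- dialect$columns
  ln <- line_no[keep]
  ts_raw <- mat[, "timestamp"]
  ts <- as.POSIXct(ts_raw, format = dialect$timestamp_format, tz = dialect$tz)
  bad_ts <- is.na(ts)
  if (any(bad_ts)) {
    problems <- dplyr::bind_rows(problems, tibble::tibble(
      line = ln[bad_ts],
      problem = sprintf("unparseable timestamp '%s'", ts_raw[bad_ts])
    ))
  }
  action <- mat[, "action"]
  bad_action <- !action %in% log_actions()
  if (any(bad_action)) {
    problems <- dplyr::bind_rows(problems, tibble::tibble(
      line = ln[bad_action],
      problem = sprintf("unknown action '%s'", action[bad_action])
    ))
  }
  payload <- unescape_field(mat[, "payload"], dialect$delimiter)
  bad_payload <- !nzchar(payload)
  if (any(bad_payload)) {
    problems <- dplyr::bind_rows(problems, tibble::tibble(
      line = ln[bad_payload], problem = "empty payload"
    ))
  }
  ok <- !(bad_ts | bad_action | bad_payload)
  ev <- tibble::tibble(
    session_id = unname(unescape_field(mat[ok, "session_id", drop = TRUE], dialect$delimiter)),
    institution_id = unname(unescape_field(mat[ok, "institution_id", drop = TRUE], dialect$delimiter)),
    timestamp = unname(ts[ok]),
    action = unname(action[ok]),
    payload = unname(payload[ok])
  )
  if (nrow(problems) == 0) ev <- validate_log_events(ev)
  list(events = ev, problems = dplyr::arrange(problems, .data$line))
}

#' Write a usage log
#'
#' Inverse of [read_log()]: `read_log(write_log(ev, f), dialect)` recovers
#' `ev` exactly, including payloads containing the delimiter (escaped on
#' write).
#'
#' @param events A `log_events` tibble.
#' @param path Output path.
#' @param dialect A [log_dialect()].
#' @return `path`, invisibly.
#' @export
write_log <- function(events, path, dialect = log_dialect()) {
  events <- validate_log_events(tibble::as_tibble(events))
  cols <- lapply(dialect$columns, function(cn) {
    x <- events[[cn]]
    if (cn == "timestamp") {
      format(x, format = dialect$timestamp_format, tz = dialect$tz)
    } else {
      escape_field(x, dialect$delimiter)
    }
  })
  lines <- do.call(paste, c(cols, sep = dialect$delimiter))
  header <- if (dialect$header) paste0("#", paste(dialect$columns, collapse = dialect$delimiter)) else character(0)
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

#' Group events into time-ordered sessions
#'
#' Partitions events by session identifier and orders each session's events
#' by timestamp, breaking ties by input order (stable). Sessions are
#' returned in order of first appearance in the input. Session identity is
#' taken as given; no inactivity-timeout splitting is attempted.
#'
#' @param events A `log_events` tibble.
#' @return A named list of per-session tibbles, each time-ordered.
#' @export
group_sessions <- function(events) {
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0) return(stats::setNames(list(), character(0)))
  events$.input_order <- seq_len(nrow(events))
  ord <- order(events$timestamp, events$.input_order)
  sorted <- events[ord, ]
  ids <- unique(events$session_id)  # first-appearance order
  out <- lapply(ids, function(id) {
    s <- sorted[sorted$session_id == id, ]
    s$.input_order <- NULL
    s
  })
  stats::setNames(out, ids)
}

#' Validate a log file and summarise its contents
#'
#' Non-aborting counterpart of [read_log()]: parses what it can, returns
#' per-action row counts and a diagnostics table of malformed rows.
#'
#' @inheritParams read_log
#' @return A list with `n_rows`, `action_counts`, `n_sessions`, `problems`.
#' @export
validate_log <- function(path, dialect = log_dialect()) {
  if (!file.exists(path)) stop("log file not found: ", path)
  parsed <- parse_log_lines(readLines(path, encoding = "UTF-8"), dialect)
  counts <- table(factor(parsed$events$action, levels = log_actions()))
  list(
    n_rows = nrow(parsed$events),
    action_counts = stats::setNames(as.integer(counts), names(counts)),
    n_sessions = length(unique(parsed$events$session_id)),
    problems = parsed$problems
  )
}
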