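#' Retweet event tables
#'
#' The unit record of the package is one retweet event: who retweeted whom,
#' when, in which language collection stream, with what text and embedded
#' URLs. Events travel as a tibble with columns:
#'
#' * `event_id` — opaque identifier (character)
#' * `timestamp` — `POSIXct`, UTC
#' * `retweeter_id` — user who retweeted (character)
#' * `source_user_id` — author of the retweeted tweet (character)
#' * `stream_language` — collection stream, `"en"` or `"ja"`
#' * `text` — tweet text (character)
#' * `urls` — list column of character vectors (possibly empty)
#'
#' Self-retweets (`retweeter_id == source_user_id`) are kept in the event
#' stream; they simply contribute nothing to unique-retweeter degree.
#'
#' @name retweet-events
NULL

event_columns <- c("event_id", "timestamp", "retweeter_id",
                   "source_user_id", "stream_language", "text", "urls")

stream_languages <- c("en", "ja")

parse_event_timestamp <- function(x) {
  ts <- suppressWarnings(lubridate::ymd_hms(x, tz = "UTC", quiet = TRUE))
  ts
}

validate_events <- function(events, call = rlang::caller_env()) {
  missing_cols <- setdiff(event_columns, names(events))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("events table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")), call = call)
  }
  bad_lang <- setdiff(unique(events$stream_language), stream_languages)
  if (length(bad_lang) > 0) {
    rlang::abort(paste0("unknown stream_language value(s): ",
                        paste(bad_lang, collapse = ", ")), call = call)
  }
  invisible(events)
}

as_event_tibble <- function(df) {
  tibble::tibble(
    event_id = as.character(df$event_id),
    timestamp = df$timestamp,
    retweeter_id = as.character(df$retweeter_id),
    source_user_id = as.character(df$source_user_id),
    stream_language = as.character(df$stream_language),
    text = as.character(df$text),
    urls = df$urls
  )
}

#' Read retweet events from JSONL or CSV
#'
#' JSONL files carry one JSON object per line with the event field names;
#' `urls` is a JSON array. CSV files carry a header and the same columns
#' with `urls` pipe-delimited (`"u1|u2"`, empty string for none).
#' Timestamps must be ISO-8601 and are resolved to UTC. Malformed records
#' are hard errors naming the offending field and line.
#'
#' @param path path to the event file.
#' @param format `"jsonl"` or `"csv"`; defaults from the file extension.
#' @return A retweet-event tibble (see [retweet-events]) in file order.
#' @seealso [write_events()]
#' @export
read_events <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- rlang::arg_match(format)
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") read_events_jsonl(path) else read_events_csv(path)
}

required_fields <- setdiff(event_columns, "urls")

read_events_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_events())
  records <- purrr::imap(lines, function(line, i) {
    rec <- tryCatch(jsonlite::fromJSON(line, simplifyVector = TRUE),
                    error = function(e) {
                      rlang::abort(paste0("line ", i, ": invalid JSON (",
                                          conditionMessage(e), ")"))
                    })
    for (f in required_fields) {
      if (is.null(rec[[f]]) || length(rec[[f]]) != 1 || is.na(rec[[f]])) {
        rlang::abort(paste0("line ", i, ": missing required field `", f, "`"))
      }
    }
    rec$urls <- as.character(rec$urls %||% character(0))
    rec
  })
  build_events(
    purrr::map_chr(records, "event_id"),
    purrr::map_chr(records, "timestamp"),
    purrr::map_chr(records, "retweeter_id"),
    purrr::map_chr(records, "source_user_id"),
    purrr::map_chr(records, "stream_language"),
    purrr::map_chr(records, "text"),
    purrr::map(records, "urls")
  )
}

read_events_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (nrow(df) == 0) return(empty_events())
  missing_cols <- setdiff(required_fields, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("CSV is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  for (f in required_fields) {
    bad <- which(is.na(df[[f]]))
    if (length(bad) > 0) {
      rlang::abort(paste0("line ", bad[1] + 1L, ": missing required field `",
                          f, "`"))
    }
  }
  urls <- purrr::map(df$urls %||% rep("", nrow(df)), function(u) {
    if (is.na(u) || !nzchar(u)) character(0) else strsplit(u, "|", fixed = TRUE)[[1]]
  })
  build_events(df$event_id, df$timestamp, df$retweeter_id,
               df$source_user_id, df$stream_language, df$text, urls)
}

build_events <- function(event_id, timestamp, retweeter_id, source_user_id,
                         stream_language, text, urls) {
  ts <- parse_event_timestamp(timestamp)
  bad_ts <- which(is.na(ts))
  if (length(bad_ts) > 0) {
    rlang::abort(paste0("line ", bad_ts[1], ": unparseable timestamp \"",
                        timestamp[bad_ts[1]], "\""))
  }
  bad_lang <- which(!stream_language %in% stream_languages)
  if (length(bad_lang) > 0) {
    rlang::abort(paste0("line ", bad_lang[1], ": unknown stream_language \"",
                        stream_language[bad_lang[1]], "\""))
  }
  tibble::tibble(
    event_id = event_id, timestamp = ts, retweeter_id = retweeter_id,
    source_user_id = source_user_id, stream_language = stream_language,
    text = text, urls = urls
  )
}

empty_events <- function() {
  tibble::tibble(
    event_id = character(0),
    timestamp = as.POSIXct(character(0), tz = "UTC"),
    retweeter_id = character(0), source_user_id = character(0),
    stream_language = character(0), text = character(0),
    urls = list()
  )
}

#' Write retweet events to JSONL or CSV
#'
#' Inverse of [read_events()]: round-tripping preserves all field values
#' (timestamps to whole seconds, UTC).
#'
#' @param events a retweet-event tibble.
#' @param path output path.
#' @param format `"jsonl"` or `"csv"`; defaults from the file extension.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("auto", "jsonl", "csv")) {
  format <- rlang::arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  validate_events(events)
  ts <- format(events$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (format == "jsonl") {
    lines <- purrr::map_chr(seq_len(nrow(events)), function(i) {
      jsonlite::toJSON(list(
        event_id = events$event_id[i], timestamp = ts[i],
        retweeter_id = events$retweeter_id[i],
        source_user_id = events$source_user_id[i],
        stream_language = events$stream_language[i],
        text = events$text[i],
        urls = events$urls[[i]]
      ), auto_unbox = TRUE)
    })
    writeLines(lines, path, useBytes = TRUE)
  } else {
    out <- dplyr::mutate(events,
      timestamp = ts,
      urls = purrr::map_chr(.data$urls, paste, collapse = "|")
    )
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Assign each user a native language
#'
#' Every user appearing in any event (as retweeter or as retweeted source)
#' is assigned exactly one native language. A user seen in only one
#' collection stream gets that stream's language; a user seen in both gets
#' the language of the majority of their event appearances; an exact tie is
#' broken by the language of their earliest appearance, and a tie on
#' timestamp resolves to `"en"`. The rule is deterministic.
#'
#' @param events a retweet-event tibble.
#' @return A tibble with columns `user` and `native_language`.
#' @export
assign_native_language <- function(events) {
  validate_events(events)
  if (nrow(events) == 0) {
    return(tibble::tibble(user = character(0), native_language = character(0)))
  }
  appearances <- dplyr::bind_rows(
    dplyr::select(events, user = "retweeter_id", "stream_language", "timestamp"),
    dplyr::select(events, user = "source_user_id", "stream_language", "timestamp")
  )
  appearances |>
    dplyr::group_by(.data$user, .data$stream_language) |>
    dplyr::summarise(n = dplyr::n(), earliest = min(.data$timestamp),
                     .groups = "drop") |>
    # majority; tie -> earliest appearance; tie on time -> en ("en" < "ja")
    dplyr::arrange(.data$user, dplyr::desc(.data$n), .data$earliest,
                   .data$stream_language) |>
    dplyr::distinct(.data$user, .keep_all = TRUE) |>
    dplyr::select("user", native_language = "stream_language")
}

#' Month key of a timestamp
#'
#' UTC calendar year-month as `"YYYY-MM"`; month assignment is
#' deterministic because all timestamps are UTC-resolved.
#'
#' @param timestamp a `POSIXct` vector.
#' @return Character vector of month keys.
#' @export
month_key <- function(timestamp) {
  format(timestamp, "%Y-%m", tz = "UTC")
}

#' Partition events by calendar month
#'
#' Splits an event table into UTC calendar-month buckets. Every event lands
#' in exactly one bucket and the union of buckets is the input.
#'
#' @param events a retweet-event tibble.
#' @return A named list of event tibbles, names sorted month keys.
#' @export
partition_by_month <- function(events) {
  validate_events(events)
  if (nrow(events) == 0) return(stats::setNames(list(), character(0)))
  key <- month_key(events$timestamp)
  split(events, key)  # split() sorts the keys
}
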