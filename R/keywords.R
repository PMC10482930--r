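#' Default Unicode-word tokenizer
#'
#' Lowercases and extracts maximal runs of Unicode letters and digits.
#' Adequate for space-delimited languages; for Japanese, supply a
#' morphological tokenizer (or pre-tokenized text) to [count_keywords()]
#' instead — the tokenizer is a plug-in point by design.
#'
#' @param text character vector.
#' @return A list of character vectors of lowercase tokens.
#' @export
tokenize_words <- function(text) {
  stringr::str_extract_all(stringr::str_to_lower(text), "[\\p{L}\\p{N}]+")
}

#' Default stoplist
#'
#' The common and expected terms removed from keyword counts by default:
#' the collection keyword itself and generic pandemic vocabulary.
#'
#' @return A lowercase character vector.
#' @export
default_stoplist <- function() {
  c("ivermectin", "covid", "coronavirus")
}

#' Read a stoplist file
#'
#' Plain text, one token per line; blank lines ignored; lowercased.
#'
#' @param path file path.
#' @return A character vector.
#' @export
read_stoplist <- function(path) {
  x <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  tolower(x[nzchar(x)])
}

#' Monthly keyword counts
#'
#' Counts every token occurrence across the event texts (each retweet's
#' text counted once per event — no deduplication), removes stoplist
#' tokens, and reports the top-k tokens, ties broken lexicographically.
#'
#' @param events a retweet-event tibble (typically one month, one stream).
#' @param tokenizer function mapping a character vector of texts to a list
#'   of lowercase token vectors; defaults to [tokenize_words()].
#' @param stoplist lowercase tokens to exclude; defaults to
#'   [default_stoplist()].
#' @param k number of keywords to report.
#' @return A tibble `rank`, `keyword`, `count`, at most `k` rows.
#' @export
count_keywords <- function(events, tokenizer = tokenize_words,
                           stoplist = default_stoplist(), k = 10) {
  validate_events(events)
  if (nrow(events) == 0) {
    return(tibble::tibble(rank = integer(0), keyword = character(0),
                          count = integer(0)))
  }
  tokens <- unlist(tokenizer(events$text), use.names = FALSE)
  tokens <- tokens[!tokens %in% stoplist]
  if (length(tokens) == 0) {
    return(tibble::tibble(rank = integer(0), keyword = character(0),
                          count = integer(0)))
  }
  tibble::tibble(keyword = tokens) |>
    dplyr::count(.data$keyword, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$keyword) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}

#' Keyword counts for every month
#'
#' @param events a retweet-event tibble.
#' @param ... passed on to [count_keywords()].
#' @return A tibble `month`, `rank`, `keyword`, `count`.
#' @export
monthly_keywords <- function(events, ...) {
  purrr::imap(partition_by_month(events), function(ev, m) {
    dplyr::mutate(count_keywords(ev, ...), month = m, .before = 1)
  }) |>
    dplyr::bind_rows()
}
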