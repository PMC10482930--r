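youtube_hosts <- c("youtube.com", "www.youtube.com", "m.youtube.com", "youtu.be")

tracking_params <- c("fbclid", "gclid")  # plus any utm_* parameter

#' Canonicalise raw URLs
#'
#' The same article circulates with varying tracking decorations; URL
#' analyses only work if those variants collide to one canonical form.
#' Normalisation lowercases the scheme and host, removes the fragment,
#' strips tracking query parameters (`utm_*`, `fbclid`, `gclid`) while
#' keeping all other parameters in their original order, and removes a
#' trailing slash from the path. Scheme-less strings are assumed `https`.
#' The operation is idempotent: `normalize_url(canonical) == canonical`.
#'
#' @param raw character vector of raw URL strings.
#' @return A tibble with one row per input: `raw`, `canonical`, `host`,
#'   `is_youtube`, `valid`. Strings with no parseable host are flagged
#'   `valid = FALSE` (with `NA` canonical) rather than erroring; URL
#'   analyses drop them.
#' @examples
#' normalize_url("HTTPS://Example.com/a/?utm_source=x#frag")$canonical
#' normalize_url("https://youtu.be/abc")$is_youtube
#' @export
normalize_url <- function(raw) {
  stopifnot(is.character(raw))
  out <- purrr::map(raw, normalize_one_url)
  tibble::tibble(
    raw = raw,
    canonical = purrr::map_chr(out, "canonical"),
    host = purrr::map_chr(out, "host"),
    is_youtube = purrr::map_lgl(out, "is_youtube"),
    valid = purrr::map_lgl(out, "valid")
  )
}

invalid_url <- list(canonical = NA_character_, host = NA_character_,
                    is_youtube = FALSE, valid = FALSE)

percent_encode_nonascii <- function(u) {
  if (!grepl("[^\\x01-\\x7f]", u, perl = TRUE)) return(u)
  chars <- strsplit(u, "", fixed = FALSE)[[1]]
  enc <- vapply(chars, function(ch) {
    if (grepl("[^\\x01-\\x7f]", ch, perl = TRUE)) {
      utils::URLencode(ch, reserved = TRUE)
    } else ch
  }, character(1), USE.NAMES = FALSE)
  paste(enc, collapse = "")
}

normalize_one_url <- function(u) {
  if (is.na(u) || !nzchar(trimws(u))) return(invalid_url)
  # raw links pasted from tweets may carry literal non-ASCII characters,
  # which the parser rejects; percent-encode them first
  u <- percent_encode_nonascii(trimws(u))
  if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*://", u)) u <- paste0("https://", u)
  parts <- tryCatch(xml2::url_parse(u), error = function(e) NULL)
  if (is.null(parts)) return(invalid_url)
  host <- tolower(parts$server)
  # a host must look like a hostname: dot-separated labels, no spaces
  if (!grepl("^[a-z0-9]([a-z0-9-]*[a-z0-9])?(\\.[a-z0-9]([a-z0-9-]*[a-z0-9])?)+$",
             host)) {
    return(invalid_url)
  }
  scheme <- tolower(parts$scheme)
  # the parser percent-decodes; re-encode unsafe characters so the
  # canonical form is itself parseable (and normalisation idempotent)
  path <- utils::URLencode(parts$path, reserved = FALSE)
  path <- sub("/+$", "", path)
  query <- utils::URLencode(parts$query, reserved = FALSE)
  if (nzchar(query)) {
    params <- strsplit(query, "&", fixed = TRUE)[[1]]
    keys <- sub("=.*$", "", params)
    keep <- !(grepl("^utm_", keys, ignore.case = TRUE) |
                tolower(keys) %in% tracking_params)
    query <- paste(params[keep], collapse = "&")
  }
  port <- if (!is.na(parts$port) && nzchar(as.character(parts$port)) &&
              as.character(parts$port) != "") paste0(":", parts$port) else ""
  canonical <- paste0(scheme, "://", host, port, path,
                      if (nzchar(query)) paste0("?", query) else "")
  list(canonical = canonical, host = host,
       is_youtube = host %in% youtube_hosts, valid = TRUE)
}

#' Tag the content language of URLs
#'
#' Resolution order per URL: an explicit override table wins; otherwise a
#' user-supplied detector function is consulted; otherwise a deterministic
#' heuristic on the URL string is used — any Hiragana, Katakana or CJK
#' codepoint, or a `.jp` host, means `"ja"`, else `"en"`. A detector
#' returning anything other than `"en"`/`"ja"` yields `"other"`.
#'
#' @param urls character vector of canonical URLs.
#' @param detector optional function `character(1) -> character(1)`
#'   returning a language code (e.g. a langdetect-style plug-in applied to
#'   fetched page content); `NULL` to rely on the heuristic.
#' @param overrides optional named character vector or two-column data
#'   frame (`canonical`, `language`) of hard assignments.
#' @return Character vector of `"en"`, `"ja"` or `"other"`, same length as
#'   `urls`. Results for repeated URLs are computed once and reused.
#' @export
detect_url_language <- function(urls, detector = NULL, overrides = NULL) {
  stopifnot(is.character(urls))
  if (is.data.frame(overrides)) {
    overrides <- stats::setNames(as.character(overrides$language),
                                 overrides$canonical)
  }
  uniq <- unique(urls)
  lang <- purrr::map_chr(uniq, function(u) {
    if (!is.null(overrides) && u %in% names(overrides)) {
      return(normalize_language_code(overrides[[u]]))
    }
    if (!is.null(detector)) {
      det <- tryCatch(detector(u), error = function(e) NA_character_)
      if (!is.na(det) && nzchar(det)) return(normalize_language_code(det))
    }
    url_language_heuristic(u)
  })
  lang[match(urls, uniq)]
}

normalize_language_code <- function(x) {
  x <- tolower(as.character(x)[1])
  if (x %in% c("en", "ja")) x else "other"
}

url_language_heuristic <- function(u) {
  if (is.na(u)) return("other")
  # Hiragana, Katakana, CJK ideographs anywhere in the (possibly
  # percent-decoded) URL string
  decoded <- tryCatch(utils::URLdecode(u), error = function(e) u)
  if (stringr::str_detect(decoded, "[\\p{Hiragana}\\p{Katakana}\\p{Han}]")) {
    return("ja")
  }
  host <- sub("^[a-z0-9+.-]+://", "", tolower(u))
  host <- sub("[/?#].*$", "", host)
  if (grepl("\\.jp(:[0-9]+)?$", host)) return("ja")
  "en"
}
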