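#' Per-URL cross-lingual diffusion records
#'
#' Restricts the event stream to URL-bearing retweets by pro-use users,
#' canonicalises the URLs, and aggregates per URL and per community (the
#' retweeter's native language): total retweet counts, daily retweet
#' series on UTC calendar days, and first-post days. A record is flagged
#' `shared` when both communities retweeted it at least once.
#'
#' @param events a retweet-event tibble (full period).
#' @param labels stance labels (`user`, `stance`), e.g. from
#'   [propagate_stance()] for both communities combined.
#' @param language_map native-language table (`user`, `native_language`)
#'   from [assign_native_language()].
#' @param detector,overrides passed to [detect_url_language()].
#' @return A tibble with one row per canonical URL: `canonical`,
#'   `url_language`, `is_youtube`, `retweets_en`, `retweets_ja`,
#'   `first_post_day_en`, `first_post_day_ja` (`Date`, `NA` when never
#'   posted there), `shared`, and a `daily` list column of per-community
#'   daily series (`community`, `day`, `n`).
#' @export
build_url_records <- function(events, labels, language_map,
                              detector = NULL, overrides = NULL) {
  validate_events(events)
  pro_users <- labels$user[labels$stance == "pro_use"]
  long <- events |>
    dplyr::filter(.data$retweeter_id %in% pro_users,
                  purrr::map_int(.data$urls, length) > 0) |>
    dplyr::select("retweeter_id", "timestamp", "urls") |>
    tidyr::unnest_longer("urls", values_to = "raw")
  if (nrow(long) == 0) return(empty_url_records())
  norm <- normalize_url(long$raw)
  long <- long |>
    dplyr::mutate(canonical = norm$canonical, is_youtube = norm$is_youtube,
                  valid = norm$valid) |>
    dplyr::filter(.data$valid) |>
    dplyr::left_join(language_map, by = c(retweeter_id = "user")) |>
    dplyr::filter(!is.na(.data$native_language)) |>
    dplyr::mutate(day = as.Date(lubridate::floor_date(.data$timestamp, "day")))
  if (nrow(long) == 0) return(empty_url_records())

  daily <- long |>
    dplyr::count(.data$canonical, .data$is_youtube,
                 community = .data$native_language, .data$day, name = "n")

  per_comm <- daily |>
    dplyr::group_by(.data$canonical, .data$is_youtube, .data$community) |>
    dplyr::summarise(retweets = sum(.data$n), first_post_day = min(.data$day),
                     .groups = "drop")

  records <- per_comm |>
    tidyr::pivot_wider(
      id_cols = c("canonical", "is_youtube"),
      names_from = "community",
      values_from = c("retweets", "first_post_day"),
      values_fill = list(retweets = 0L)
    )
  for (col in c("retweets_en", "retweets_ja")) {
    if (!col %in% names(records)) records[[col]] <- 0L
  }
  for (col in c("first_post_day_en", "first_post_day_ja")) {
    if (!col %in% names(records)) records[[col]] <- as.Date(NA)
  }
  nested <- daily |>
    dplyr::select("canonical", "community", "day", "n") |>
    tidyr::nest(daily = c("community", "day", "n"))

  records |>
    dplyr::mutate(
      url_language = detect_url_language(.data$canonical, detector = detector,
                                         overrides = overrides),
      shared = .data$retweets_en > 0 & .data$retweets_ja > 0
    ) |>
    dplyr::left_join(nested, by = "canonical") |>
    dplyr::select("canonical", "url_language", "is_youtube",
                  "retweets_en", "retweets_ja",
                  "first_post_day_en", "first_post_day_ja",
                  "shared", "daily") |>
    dplyr::arrange(.data$canonical)
}

empty_url_records <- function() {
  tibble::tibble(
    canonical = character(0), url_language = character(0),
    is_youtube = logical(0), retweets_en = integer(0),
    retweets_ja = integer(0),
    first_post_day_en = as.Date(character(0)),
    first_post_day_ja = as.Date(character(0)),
    shared = logical(0), daily = list()
  )
}

#' Non-native URL sharing and influence ranking
#'
#' For each pro-use user, counts the distinct canonical URLs they
#' retweeted whose content language differs from their native language,
#' and attaches their full-period unique-retweeter degree and degree
#' rank. The top sharers of non-native content, and how influential they
#' are, characterise who carries information across the language border.
#'
#' @inheritParams build_url_records
#' @param records output of [build_url_records()] (supplies URL
#'   languages).
#' @param degree_table full-period degree table from
#'   [build_degree_table()].
#' @param top_n number of users to keep (top sharers; default 200), ties
#'   broken lexicographically.
#' @return A tibble `user`, `native_language`, `n_unique_nonnative_urls`,
#'   `degree`, `degree_rank`.
#' @export
nonnative_share_ranking <- function(records, events, labels, language_map,
                                    degree_table, top_n = 200) {
  validate_events(events)
  pro_users <- labels$user[labels$stance == "pro_use"]
  url_lang <- dplyr::select(records, "canonical", "url_language")
  long <- events |>
    dplyr::filter(.data$retweeter_id %in% pro_users,
                  purrr::map_int(.data$urls, length) > 0) |>
    dplyr::select(user = "retweeter_id", "urls") |>
    tidyr::unnest_longer("urls", values_to = "raw")
  if (nrow(long) == 0) {
    return(tibble::tibble(user = character(0), native_language = character(0),
                          n_unique_nonnative_urls = integer(0),
                          degree = integer(0), degree_rank = integer(0)))
  }
  norm <- normalize_url(long$raw)
  ranks <- degree_table |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$user) |>
    dplyr::mutate(degree_rank = dplyr::row_number())
  shares <- long |>
    dplyr::mutate(canonical = norm$canonical, valid = norm$valid) |>
    dplyr::filter(.data$valid) |>
    dplyr::inner_join(url_lang, by = "canonical") |>
    dplyr::left_join(language_map, by = "user") |>
    dplyr::filter(!is.na(.data$native_language))
  # every pro-use URL sharer appears; native-only sharers get count 0
  shares |>
    dplyr::mutate(nonnative = .data$url_language %in% c("en", "ja") &
                    .data$url_language != .data$native_language) |>
    dplyr::group_by(.data$user, .data$native_language) |>
    dplyr::summarise(
      n_unique_nonnative_urls =
        dplyr::n_distinct(.data$canonical[.data$nonnative]),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_unique_nonnative_urls), .data$user) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::left_join(ranks, by = "user") |>
    dplyr::mutate(degree = dplyr::coalesce(.data$degree, 0L))
}

#' Cubic smoothing-spline series smoother
#'
#' Smooths an ordered numeric sequence (e.g. the node degrees of the top
#' non-native URL sharers, which vary wildly user to user) with a cubic
#' smoothing spline evaluated at the input positions. `smoothing = 0`
#' reproduces the input exactly.
#'
#' @param values ordered numeric sequence, at least 4 points for actual
#'   smoothing (fewer are returned unchanged with a warning).
#' @param smoothing non-negative smoothing parameter (the spline's
#'   `lambda`); larger values give a stiffer curve.
#' @return Numeric vector, same length as `values`.
#' @export
smooth_series <- function(values, smoothing = 1e-4) {
  stopifnot(is.numeric(values), is.numeric(smoothing), smoothing >= 0)
  if (length(values) < 4) {
    rlang::warn("fewer than 4 points: returning the input unsmoothed.")
    return(values)
  }
  if (smoothing == 0) return(values)
  if (stats::var(values) == 0) return(values)  # constant in, constant out
  fit <- stats::smooth.spline(seq_along(values), values,
                              lambda = smoothing, all.knots = TRUE)
  stats::predict(fit, seq_along(values))$y
}

#' Cross-lingual diffusion-timing observations
#'
#' For every URL retweeted by pro-use users of both communities, compares
#' the timing in the URL's own language community (day 0 = its first post
#' there) with the other community's adoption: `day_diff_first` is the
#' non-native first-post day minus day 0, and `day_diff_peak` is the
#' earliest day on which the non-native daily retweet series attains its
#' maximum, minus day 0. Negative values mean the non-native community
#' led. URLs whose detected language is neither `en` nor `ja` are
#' skipped.
#'
#' @param records output of [build_url_records()]; only rows with
#'   `shared = TRUE` contribute.
#' @param youtube_excluded if `TRUE`, drop YouTube-host URLs first
#'   (their page language follows the viewer's location, so string-based
#'   tagging is unreliable for them).
#' @return A tibble `canonical`, `direction`
#'   (`"en_url_adopted_by_ja"`/`"ja_url_adopted_by_en"`),
#'   `day_diff_first`, `day_diff_peak`; class `timing_observations`.
#' @export
timing_observations <- function(records, youtube_excluded = FALSE) {
  stopifnot(all(c("canonical", "url_language", "is_youtube", "shared",
                  "daily") %in% names(records)))
  recs <- dplyr::filter(records, .data$shared,
                        .data$url_language %in% c("en", "ja"))
  if (youtube_excluded) recs <- dplyr::filter(recs, !.data$is_youtube)
  out <- purrr::map(seq_len(nrow(recs)), function(i) {
    r <- recs[i, ]
    native <- r$url_language
    nonnative <- if (native == "en") "ja" else "en"
    day0 <- if (native == "en") r$first_post_day_en else r$first_post_day_ja
    nn_first <- if (native == "en") r$first_post_day_ja else r$first_post_day_en
    if (is.na(day0) || is.na(nn_first)) return(NULL)  # absent in one community
    series <- r$daily[[1]]
    nn <- series[series$community == nonnative, ]
    peak_day <- min(nn$day[nn$n == max(nn$n)])  # earliest day attaining the max
    tibble::tibble(
      canonical = r$canonical,
      direction = if (native == "en") "en_url_adopted_by_ja" else "ja_url_adopted_by_en",
      day_diff_first = as.integer(nn_first - day0),
      day_diff_peak = as.integer(peak_day - day0)
    )
  }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) {
    out <- tibble::tibble(canonical = character(0), direction = character(0),
                          day_diff_first = integer(0),
                          day_diff_peak = integer(0))
  }
  class(out) <- c("timing_observations", class(out))
  out
}
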