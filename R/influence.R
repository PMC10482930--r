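#' Unique-retweeter degree table
#'
#' The influence measure is the number of distinct users who retweeted a
#' given user within the window: for each `source_user_id`, the count of
#' distinct `retweeter_id` values, excluding self-retweets. Users who only
#' appear as retweeters get degree 0, so the table covers every user seen
#' in the window.
#'
#' @param events a retweet-event tibble, typically one month and one
#'   language stream (the function itself does not subset).
#' @return A tibble with columns `user` and `degree`, sorted by user.
#' @export
build_degree_table <- function(events) {
  validate_events(events)
  degrees <- events |>
    dplyr::filter(.data$retweeter_id != .data$source_user_id) |>
    dplyr::distinct(.data$source_user_id, .data$retweeter_id) |>
    dplyr::count(user = .data$source_user_id, name = "degree")
  all_users <- unique(c(events$retweeter_id, events$source_user_id))
  tibble::tibble(user = all_users) |>
    dplyr::left_join(degrees, by = "user") |>
    dplyr::mutate(degree = dplyr::coalesce(.data$degree, 0L)) |>
    dplyr::arrange(.data$user)
}

#' Top-k influence ranking
#'
#' Ranks users by unique-retweeter degree, ties broken by lexicographic
#' user identifier so rankings are reproducible inputs for rank-similarity
#' scores.
#'
#' @param degree_table a tibble with columns `user`, `degree`
#'   (from [build_degree_table()]).
#' @param k number of users to rank.
#' @return A tibble `rank`, `user`, `degree` with non-increasing degrees.
#'   If fewer than `k` users exist the full list is returned with
#'   attribute `short = TRUE`.
#' @export
influence_ranking <- function(degree_table, k) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  ranked <- degree_table |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$user) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  attr(ranked, "short") <- nrow(ranked) < k
  ranked
}

#' Monthly influence rankings
#'
#' Convenience wrapper: partitions events by UTC calendar month (and,
#' optionally, by collection stream), builds the degree table for each
#' month, and returns the top-k ranking per month.
#'
#' @param events a retweet-event tibble.
#' @param k ranking depth (default 10, the usual monthly leaderboard).
#' @param by_stream if `TRUE`, rank each language stream separately.
#' @return A tibble `month` (+ `stream_language`), `rank`, `user`,
#'   `degree`.
#' @export
monthly_rankings <- function(events, k = 10, by_stream = FALSE) {
  validate_events(events)
  groups <- if (by_stream) {
    split(events, list(month_key(events$timestamp), events$stream_language),
          sep = "\r", drop = TRUE)
  } else {
    partition_by_month(events)
  }
  purrr::imap(groups, function(ev, key) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    ranked <- influence_ranking(build_degree_table(ev), k)
    ranked$month <- parts[1]
    if (by_stream) ranked$stream_language <- parts[2]
    ranked
  }) |>
    dplyr::bind_rows() |>
    dplyr::relocate("month")
}
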