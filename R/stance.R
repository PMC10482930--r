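stance_levels <- c("pro_use", "anti_use", "undetermined")

#' Propagate stance labels through the retweet graph
#'
#' Starting from manually tagged seed users (hop 0), labels spread
#' outward one hop at a time: at hop `h`, every still-unlabelled user who
#' retweeted at least one determinately labelled (pro or anti) user is
#' assigned a stance by majority of their retweet events — counted with
#' multiplicity — whose source carried a pro vs anti label at the end of
#' hop `h - 1`. A strict majority gives that stance; an exact tie gives
#' `undetermined`. Undetermined users never transmit labels onward, and a
#' label never changes once assigned (seeds included), which makes the
#' result independent of within-hop order. Propagation stops at
#' `max_hops` or when a hop labels no one.
#'
#' @param events full-period retweet events for one language community.
#' @param seeds a tibble with columns `user`, `stance`
#'   (`"pro_use"`/`"anti_use"`/`"undetermined"`); duplicated users keep
#'   their first row. Seeds absent from the event set are kept (with a
#'   warning) — they simply have no one to infect.
#' @param max_hops maximum hop count (the reference configuration is 6
#'   for English and 5 for Japanese).
#' @return A tibble `user`, `stance`, `hop`, `is_seed` covering every
#'   labelled user (seeds included; users never reached are absent).
#' @export
propagate_stance <- function(events, seeds, max_hops) {
  validate_events(events)
  stopifnot(is.numeric(max_hops), max_hops >= 1)
  if (!all(c("user", "stance") %in% names(seeds)) || nrow(seeds) == 0) {
    rlang::abort("`seeds` must be a non-empty tibble with columns `user`, `stance`.")
  }
  bad <- setdiff(unique(seeds$stance), stance_levels)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown stance value(s): ", paste(bad, collapse = ", ")))
  }
  seeds <- dplyr::distinct(seeds, .data$user, .keep_all = TRUE)
  known_users <- unique(c(events$retweeter_id, events$source_user_id))
  if (!all(seeds$user %in% known_users)) {
    rlang::warn(paste0(sum(!seeds$user %in% known_users),
                       " seed user(s) absent from the event set; kept."))
  }

  # retweet multiplicity per (retweeter, source)
  edges <- dplyr::count(events, .data$retweeter_id, .data$source_user_id,
                        name = "times")

  stance <- stats::setNames(seeds$stance, seeds$user)
  hop <- stats::setNames(rep(0L, nrow(seeds)), seeds$user)

  for (h in seq_len(max_hops)) {
    transmitting <- names(stance)[stance %in% c("pro_use", "anti_use")]
    votes <- edges |>
      dplyr::filter(.data$source_user_id %in% transmitting,
                    !.data$retweeter_id %in% names(stance)) |>
      dplyr::mutate(src_stance = unname(stance[.data$source_user_id])) |>
      dplyr::group_by(.data$retweeter_id) |>
      dplyr::summarise(
        pro = sum(.data$times[.data$src_stance == "pro_use"]),
        anti = sum(.data$times[.data$src_stance == "anti_use"]),
        .groups = "drop"
      )
    if (nrow(votes) == 0) break
    new_stance <- dplyr::case_when(
      votes$pro > votes$anti ~ "pro_use",
      votes$anti > votes$pro ~ "anti_use",
      TRUE ~ "undetermined"
    )
    stance <- c(stance, stats::setNames(new_stance, votes$retweeter_id))
    hop <- c(hop, stats::setNames(rep(h, nrow(votes)), votes$retweeter_id))
  }

  users_out <- names(stance)
  tibble::tibble(
    user = users_out,
    stance = unname(stance),
    hop = as.integer(unname(hop[users_out])),
    is_seed = users_out %in% seeds$user
  ) |>
    dplyr::arrange(.data$hop, .data$user)
}

#' Population coverage of stance propagation
#'
#' Coverage is the share of the user population assigned a determinate
#' (pro or anti) stance. Percentages are rounded to one decimal for
#' reporting; the raw fractions are kept alongside.
#'
#' @param n_pro,n_anti counts of pro-use and anti-use labelled users.
#' @param total_users population size; must be at least `n_pro + n_anti`.
#' @return A one-row tibble: `total_users`, `n_pro`, `n_anti`,
#'   `coverage_pct`, `pro_share_pct` (pro share among labelled users),
#'   plus unrounded `coverage_raw`, `pro_share_raw`.
#' @examples
#' coverage_stats(280713, 206428, 698484)$coverage_pct  # 69.7
#' @export
coverage_stats <- function(n_pro, n_anti, total_users) {
  if (total_users <= 0) rlang::abort("`total_users` must be positive.")
  if (n_pro + n_anti > total_users) {
    rlang::abort("labelled users exceed `total_users`.")
  }
  labelled <- n_pro + n_anti
  coverage <- 100 * labelled / total_users
  pro_share <- if (labelled > 0) 100 * n_pro / labelled else 0
  tibble::tibble(
    total_users = total_users, n_pro = n_pro, n_anti = n_anti,
    coverage_pct = round(coverage, 1), pro_share_pct = round(pro_share, 1),
    coverage_raw = coverage, pro_share_raw = pro_share
  )
}

#' Coverage from a propagated label table
#'
#' @param labels output of [propagate_stance()].
#' @param total_users population size (distinct users in the community).
#' @return See [coverage_stats()].
#' @export
coverage_from_labels <- function(labels, total_users) {
  coverage_stats(
    n_pro = sum(labels$stance == "pro_use"),
    n_anti = sum(labels$stance == "anti_use"),
    total_users = total_users
  )
}

#' Stance composition of the monthly top-k
#'
#' For each month, counts how many of the top-k ranked users carry each
#' stance; top-k users without a label count as undetermined, so the three
#' counts always sum to the size of that month's list.
#'
#' @param rankings monthly rankings (`month`, `rank`, `user`).
#' @param labels stance labels (`user`, `stance`).
#' @param k depth to examine (default 10).
#' @return A tibble `month`, `n_pro`, `n_anti`, `n_undetermined`, `n_top`;
#'   class `stance_timeseries`.
#' @export
stance_timeseries <- function(rankings, labels, k = 10) {
  stopifnot(all(c("month", "rank", "user") %in% names(rankings)),
            all(c("user", "stance") %in% names(labels)))
  out <- rankings |>
    dplyr::group_by(.data$month) |>
    dplyr::arrange(.data$rank, .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup() |>
    dplyr::left_join(dplyr::select(labels, "user", "stance"), by = "user") |>
    dplyr::mutate(stance = dplyr::coalesce(.data$stance, "undetermined")) |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(
      n_pro = sum(.data$stance == "pro_use"),
      n_anti = sum(.data$stance == "anti_use"),
      n_undetermined = sum(.data$stance == "undetermined"),
      n_top = dplyr::n(),
      .groups = "drop"
    )
  class(out) <- c("stance_timeseries", class(out))
  out
}
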