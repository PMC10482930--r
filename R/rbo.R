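#' Rank Biased Overlap between two ranked lists
#'
#' RBO measures the similarity of two rankings as a geometrically weighted
#' average of prefix-overlap proportions,
#' \deqn{RBO(S, T, p) = (1 - p) \sum_{d \ge 1} p^{d-1} A_d,}
#' where \eqn{A_d} is the fraction of the top-\eqn{d} prefixes of `s` and
#' `t` that agree (\eqn{|prefix_d(S) \cap prefix_d(T)| / d}). Smaller `p`
#' concentrates the weight near the top of the lists, so disagreements
#' among the highest-ranked items are penalised hardest.
#'
#' The `truncated` variant sums to `depth` only; its value for identical
#' lists is \eqn{1 - p^{depth}}, not 1. The `extrapolated` variant adds
#' \eqn{p^{depth} A_{depth}}, the bounded extension under which identical
#' lists score exactly 1.
#'
#' @param s,t character vectors: ranked lists (rank 1 first), no
#'   duplicates within a list.
#' @param p weight parameter in (0, 1); default 0.9, the conventional
#'   choice giving the top 10 ranks ~86% of the weight.
#' @param depth evaluation depth, at most `min(length(s), length(t))`;
#'   defaults to that minimum.
#' @param variant `"extrapolated"` (default) or `"truncated"`.
#' @return A one-row tibble `score`, `p`, `depth`, `variant`.
#' @examples
#' rbo(c("a", "b"), c("b", "a"), p = 0.5, variant = "truncated")  # 0.25
#' rbo(letters[1:5], letters[1:5])$score                          # 1
#' @export
rbo <- function(s, t, p = 0.9, depth = NULL,
                variant = c("extrapolated", "truncated")) {
  variant <- rlang::arg_match(variant)
  depth <- depth %||% min(length(s), length(t))
  score <- rbo_score(s, t, p = p, depth = depth, variant = variant)
  tibble::tibble(score = score, p = p, depth = as.integer(depth),
                 variant = variant)
}

#' Bare-numeric RBO score
#'
#' Same computation as [rbo()] without the tibble wrapper; useful in tight
#' loops.
#'
#' @inheritParams rbo
#' @return A number in \[0, 1\].
#' @export
rbo_score <- function(s, t, p = 0.9, depth = min(length(s), length(t)),
                      variant = "extrapolated") {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1) {
    rlang::abort("`p` must be a single number strictly between 0 and 1.")
  }
  if (anyDuplicated(s) || anyDuplicated(t)) {
    rlang::abort("ranked lists must not contain duplicate entries.")
  }
  if (depth < 1 || depth > min(length(s), length(t))) {
    rlang::abort("`depth` must be between 1 and the shorter list length.")
  }
  s <- as.character(s)
  t <- as.character(t)
  a_d <- vapply(seq_len(depth), function(d) {
    length(intersect(s[seq_len(d)], t[seq_len(d)])) / d
  }, numeric(1))
  score <- (1 - p) * sum(p^(seq_len(depth) - 1) * a_d)
  if (variant == "extrapolated") score <- score + p^depth * a_d[depth]
  score
}

#' Month-over-month RBO churn series
#'
#' Scores each consecutive pair of monthly influence rankings; the score
#' is attributed to the later month. High values mean the influencer set
#' persisted; values near 0 mean wholesale turnover.
#'
#' @param rankings a tibble of monthly rankings with columns `month`,
#'   `rank`, `user` (as from [monthly_rankings()], one language at a
#'   time).
#' @param p,depth,variant passed to [rbo()]; `depth` defaults to the
#'   ranking depth `k`, shortened when a month has fewer users.
#' @param k ranking depth to compare (default 10).
#' @return A tibble `month`, `score`, `p`, `depth`, `variant`, `short`
#'   (`TRUE` when either month's list was shorter than `k`); class
#'   `rbo_series`. Empty for fewer than two months.
#' @export
monthly_rbo_series <- function(rankings, p = 0.9, k = 10,
                               variant = c("extrapolated", "truncated"),
                               depth = NULL) {
  variant <- rlang::arg_match(variant)
  stopifnot(all(c("month", "rank", "user") %in% names(rankings)))
  months <- sort(unique(rankings$month))
  lists <- purrr::map(months, function(m) {
    rankings |>
      dplyr::filter(.data$month == m) |>
      dplyr::arrange(.data$rank) |>
      dplyr::slice_head(n = k) |>
      dplyr::pull("user")
  })
  if (length(months) < 2) {
    out <- tibble::tibble(month = character(0), score = numeric(0),
                          p = numeric(0), depth = integer(0),
                          variant = character(0), short = logical(0))
    class(out) <- c("rbo_series", class(out))
    return(out)
  }
  out <- purrr::map(seq_len(length(months) - 1), function(i) {
    s <- lists[[i]]
    t <- lists[[i + 1]]
    d <- min(depth %||% k, length(s), length(t))
    res <- rbo(s, t, p = p, depth = d, variant = variant)
    dplyr::mutate(res, month = months[i + 1],
                  short = length(s) < k || length(t) < k, .before = 1)
  }) |>
    dplyr::bind_rows() |>
    dplyr::relocate("month", "score")
  class(out) <- c("rbo_series", class(out))
  out
}
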