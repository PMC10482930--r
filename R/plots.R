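#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a month-over-month RBO churn series
#'
#' @param object an `rbo_series` tibble from [monthly_rbo_series()] (a
#'   `stream_language` column, if present, becomes the colour aesthetic).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.rbo_series <- function(object, ...) {
  p <- if ("stream_language" %in% names(object)) {
    ggplot2::ggplot(object, ggplot2::aes(.data$month, .data$score,
                                         colour = .data$stream_language,
                                         group = .data$stream_language))
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data$month, .data$score, group = 1))
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "month", y = "RBO score", colour = "stream",
                  title = "Influencer-set similarity, month over month") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the stance composition of the monthly top-k
#'
#' @param object a `stance_timeseries` tibble from [stance_timeseries()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.stance_timeseries <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("n_pro", "n_anti", "n_undetermined"),
                        names_to = "stance", values_to = "count") |>
    dplyr::mutate(stance = dplyr::recode(.data$stance, n_pro = "pro_use",
                                         n_anti = "anti_use",
                                         n_undetermined = "undetermined"))
  ggplot2::ggplot(long, ggplot2::aes(.data$month, .data$count,
                                     colour = .data$stance,
                                     group = .data$stance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(pro_use = "#c0392b",
                                            anti_use = "#27ae60",
                                            undetermined = "grey50")) +
    ggplot2::labs(x = "month", y = "users in top-k",
                  title = "Stance of the monthly top influencers") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    (if ("stream_language" %in% names(object))
      ggplot2::facet_wrap(~stream_language) else NULL)
}

#' Plot diffusion-timing day differences with an optional fitted ALD
#'
#' Histogram (density scale) of first-post day differences, faceted by
#' direction, optionally overlaid with a fitted asymmetric Laplace
#' density.
#'
#' @param object a `timing_observations` tibble from
#'   [timing_observations()].
#' @param fit optional `ald_fit` to overlay.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.timing_observations <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$day_diff_first)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = 1, fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "day difference (non-native minus native first post)",
                  y = "density",
                  title = "Cross-lingual adoption timing") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "ald_fit"))
    rng <- range(object$day_diff_first)
    grid <- tibble::tibble(
      x = seq(rng[1], rng[2], length.out = 400),
      y = dald(seq(rng[1], rng[2], length.out = 400),
               fit$location, fit$scale, fit$asymmetry)
    )
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(.data$x, .data$y),
                                inherit.aes = FALSE, colour = "firebrick")
  }
  p
}

#' Plot a fitted asymmetric Laplace distribution over its data
#'
#' @param object an `ald_fit` from [fit_asymmetric_laplace()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ald_fit <- function(object, ...) {
  dat <- tibble::tibble(x = object$x)
  rng <- range(object$x)
  grid <- tibble::tibble(
    x = seq(rng[1], rng[2], length.out = 400),
    y = dald(seq(rng[1], rng[2], length.out = 400),
             object$location, object$scale, object$asymmetry)
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = 1, fill = "grey70", colour = "white") +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$x, .data$y),
                       colour = "firebrick") +
    ggplot2::labs(x = "value", y = "density",
                  title = "Asymmetric Laplace fit") +
    ggplot2::theme_minimal()
}

#' Plot the non-native sharing ranking with spline-smoothed degree
#'
#' Two panels in the spirit of a sharing/influence comparison: the count
#' of distinct non-native URLs per top user, and the (smoothed) degree
#' rank of those same users, coloured by native language.
#'
#' @param ranking output of [nonnative_share_ranking()].
#' @param smoothing passed to [smooth_series()] for the degree-rank
#'   panel.
#' @return A ggplot.
#' @export
plot_nonnative_ranking <- function(ranking, smoothing = 1e-3) {
  dat <- ranking |>
    dplyr::group_by(.data$native_language) |>
    dplyr::arrange(dplyr::desc(.data$n_unique_nonnative_urls),
                   .by_group = TRUE) |>
    dplyr::mutate(
      position = dplyr::row_number(),
      degree_rank_smooth = if (dplyr::n() >= 4)
        smooth_series(as.numeric(.data$degree_rank), smoothing)
      else as.numeric(.data$degree_rank)
    ) |>
    dplyr::ungroup() |>
    tidyr::pivot_longer(c("n_unique_nonnative_urls", "degree_rank_smooth"),
                        names_to = "panel", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(.data$position, .data$value,
                                    colour = .data$native_language)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "user (ordered by non-native URL count)", y = NULL,
                  colour = "native language",
                  title = "Non-native URL sharing and sharer influence") +
    ggplot2::theme_minimal()
}
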