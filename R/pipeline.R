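#' Run the full analysis pipeline
#'
#' Orchestrates every stage end to end: corpus (synthetic generation or
#' ingestion of an event file), native-language assignment, monthly
#' influence rankings, monthly keyword counts, the month-over-month RBO
#' churn series, stance propagation from seeds with coverage statistics,
#' and the cross-lingual URL analysis (per-URL records, non-native
#' sharing ranking, timing observations with and without YouTube URLs,
#' and asymmetric Laplace fits). All stage outputs are written as CSV (or
#' JSON) under `out_dir` together with a run manifest; a rerun with the
#' same configuration and seed reproduces identical file content.
#'
#' The configuration is a YAML or JSON file (or an equivalent named
#' list) with fields:
#' \describe{
#'   \item{mode}{`"synthetic"` (default) or `"events"`.}
#'   \item{events, seeds}{paths to an event file and a seed-stance CSV
#'     (`user`, `stance`, `month`) — required when `mode = "events"`.}
#'   \item{synthetic}{named list of [synth_config()] overrides.}
#'   \item{seed}{integer; flows into every source of randomness.}
#'   \item{rbo}{list with `p`, `depth`, `variant`.}
#'   \item{top_k}{ranking depth (default 10).}
#'   \item{max_hops}{named list, hops per language, default
#'     `list(en = 6, ja = 5)`.}
#'   \item{youtube_excluded}{default `TRUE`; the timing analysis is
#'     written both ways regardless.}
#'   \item{top_n_nonnative}{depth of the non-native sharing ranking
#'     (default 200).}
#' }
#'
#' @param config path to a YAML/JSON configuration file, or a named list.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with every stage result plus the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- load_pipeline_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  gt <- NULL
  if (cfg$mode == "synthetic") {
    sc_args <- cfg$synthetic %||% list()
    sc_args$rng_seed <- cfg$seed
    scfg <- do.call(synth_config, sc_args)
    corpus <- generate_corpus(scfg)
    events <- corpus$events
    gt <- corpus$ground_truth
    seeds <- gt$seeds
  } else {
    events <- read_events(cfg$events)
    seeds <- readr::read_csv(cfg$seeds, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
  }

  language_map <- assign_native_language(events)

  rankings <- monthly_rankings(events, k = cfg$top_k, by_stream = TRUE)
  keywords <- monthly_keywords(events)

  rbo_series <- purrr::map(stream_languages, function(lg) {
    monthly_rbo_series(
      dplyr::filter(rankings, .data$stream_language == lg),
      p = cfg$rbo$p, k = cfg$top_k, variant = cfg$rbo$variant
    ) |>
      dplyr::mutate(stream_language = lg, .before = 1)
  }) |>
    dplyr::bind_rows()

  labels <- purrr::map(stream_languages, function(lg) {
    ev <- dplyr::filter(events, .data$stream_language == lg)
    if (nrow(ev) == 0) return(NULL)
    sd <- seeds |>
      dplyr::distinct(.data$user, .keep_all = TRUE) |>
      dplyr::semi_join(language_map[language_map$native_language == lg, ],
                       by = "user")
    if (nrow(sd) == 0) return(NULL)
    propagate_stance(ev, sd, max_hops = cfg$max_hops[[lg]]) |>
      dplyr::mutate(stream_language = lg)
  }) |>
    dplyr::bind_rows()

  coverage <- purrr::map(stream_languages, function(lg) {
    total <- sum(language_map$native_language == lg)
    if (total == 0) return(NULL)
    coverage_from_labels(labels[labels$stream_language == lg, ], total) |>
      dplyr::mutate(stream_language = lg, .before = 1)
  }) |>
    dplyr::bind_rows()

  stance_series <- purrr::map(stream_languages, function(lg) {
    stance_timeseries(
      dplyr::filter(rankings, .data$stream_language == lg),
      labels, k = cfg$top_k
    ) |>
      dplyr::mutate(stream_language = lg, .before = 1)
  }) |>
    dplyr::bind_rows()

  records <- build_url_records(events, labels, language_map)
  degree_full <- build_degree_table(events)
  nonnative <- nonnative_share_ranking(records, events, labels, language_map,
                                       degree_full, top_n = cfg$top_n_nonnative)

  timing_all <- timing_observations(records, youtube_excluded = FALSE)
  timing_noyt <- timing_observations(records, youtube_excluded = TRUE)
  timing_main <- if (isTRUE(cfg$youtube_excluded)) timing_noyt else timing_all

  ald <- NULL
  neg <- NULL
  if (nrow(timing_main) >= 10 &&
      length(unique(timing_main$day_diff_first)) > 1) {
    ald <- fit_asymmetric_laplace(timing_main$day_diff_first)
    neg <- negative_mass(timing_main$day_diff_first, ald)
  }

  write_stage_outputs(out_dir, cfg, events, language_map, rankings, keywords,
                      rbo_series, labels, coverage, stance_series, records,
                      nonnative, timing_all, timing_noyt, ald, neg)

  invisible(list(
    config = cfg, events = events, ground_truth = gt,
    language_map = language_map, rankings = rankings, keywords = keywords,
    rbo_series = rbo_series, labels = labels, coverage = coverage,
    stance_series = stance_series, url_records = records,
    nonnative_ranking = nonnative, timing_all = timing_all,
    timing_youtube_excluded = timing_noyt, ald_fit = ald,
    negative_mass = neg
  ))
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) rlang::abort(paste0("no such config: ", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) rlang::abort("`config` must be a list or a file path.")
  cfg <- list(
    mode = config$mode %||% "synthetic",
    events = config$events, seeds = config$seeds,
    synthetic = config$synthetic %||% list(),
    seed = as.integer(config$seed %||% 1L),
    rbo = utils::modifyList(list(p = 0.9, depth = 10, variant = "extrapolated"),
                            config$rbo %||% list()),
    top_k = config$top_k %||% 10,
    max_hops = utils::modifyList(list(en = 6, ja = 5),
                                 config$max_hops %||% list()),
    youtube_excluded = config$youtube_excluded %||% TRUE,
    top_n_nonnative = config$top_n_nonnative %||% 200
  )
  if (!cfg$mode %in% c("synthetic", "events")) {
    rlang::abort("`mode` must be \"synthetic\" or \"events\".")
  }
  if (cfg$mode == "events") {
    if (is.null(cfg$events)) rlang::abort("`events` path required in events mode.")
    if (is.null(cfg$seeds)) rlang::abort("`seeds` path required in events mode.")
  }
  if (!is.numeric(cfg$rbo$p) || cfg$rbo$p <= 0 || cfg$rbo$p >= 1) {
    rlang::abort("`rbo$p` must lie strictly between 0 and 1.")
  }
  if (!all(c("en", "ja") %in% names(cfg$max_hops))) {
    rlang::abort("`max_hops` must name both `en` and `ja`.")
  }
  cfg
}

write_stage_outputs <- function(out_dir, cfg, events, language_map, rankings,
                                keywords, rbo_series, labels, coverage,
                                stance_series, records, nonnative,
                                timing_all, timing_noyt, ald, neg) {
  wcsv <- function(df, name) {
    readr::write_csv(df, file.path(out_dir, name), progress = FALSE)
  }
  wcsv(language_map, "language_map.csv")
  wcsv(rankings, "influence_rankings.csv")
  wcsv(keywords, "keywords.csv")
  wcsv(rbo_series, "rbo_series.csv")
  wcsv(dplyr::select(labels, "user", "stance", "hop", "is_seed",
                     "stream_language"), "stance_labels.csv")
  wcsv(stance_series, "stance_timeseries.csv")
  wcsv(dplyr::select(records, -"daily"), "url_records.csv")
  wcsv(nonnative, "nonnative_ranking.csv")
  wcsv(timing_all, "timing_observations.csv")
  wcsv(timing_noyt, "timing_observations_noyoutube.csv")
  jsonlite::write_json(
    purrr::map(split(coverage, coverage$stream_language),
               function(r) as.list(r[setdiff(names(r), "stream_language")])),
    file.path(out_dir, "coverage.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(ald)) {
    jsonlite::write_json(list(
      location = ald$location, scale = ald$scale, asymmetry = ald$asymmetry,
      log_likelihood = ald$log_likelihood, n = ald$n,
      negative_mass_empirical = neg$empirical,
      negative_mass_model = neg$model
    ), file.path(out_dir, "ald_fit.json"), auto_unbox = TRUE, digits = NA)
  }
  cfg_plain <- cfg
  manifest <- list(
    seed = cfg$seed,
    config_hash = rlang::hash(cfg_plain),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("retlang")),
    n_events = nrow(events),
    n_users = nrow(language_map),
    n_urls = nrow(records),
    n_timing_observations = nrow(timing_all)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
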