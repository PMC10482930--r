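#' Synthetic bilingual corpus configuration
#'
#' Parameters of the generator, chosen to emulate the structure of a
#' two-community (English/Japanese) retweet collection: unequal community
#' sizes, heavy-tailed influencer attractiveness, stance homophily in
#' retweeting, a shared URL pool with per-URL language, and cross-lingual
#' adoption offsets drawn from an asymmetric Laplace law with substantial
#' lead (negative) mass.
#'
#' @param n_users_en,n_users_ja community sizes.
#' @param n_months number of calendar months, starting at `origin`.
#' @param origin first day of the corpus (a `Date`).
#' @param degree_exponent Pareto tail exponent of user attractiveness;
#'   smaller values give steeper influence decay.
#' @param n_seed_influencers_per_month number of seed users per stance
#'   and community tagged for each month (emulating manual review of the
#'   monthly top influencers).
#' @param pro_fraction probability a user's true stance is pro-use.
#' @param homophily probability a retweet targets a same-stance source.
#' @param n_urls size of the URL pool.
#' @param url_lang_en_fraction probability a URL is English-language.
#' @param youtube_fraction share of the URL pool hosted on YouTube.
#' @param ald_location,ald_scale,ald_asymmetry parameters (days, 1/days,
#'   dimensionless) of the asymmetric Laplace law for cross-lingual
#'   first-post offsets; see [dald()].
#' @param crosslingual_share_prob probability a URL is also adopted by
#'   the other community.
#' @param events_per_user_per_month mean baseline retweets per user per
#'   month.
#' @param rng_seed integer seed; identical config and seed give an
#'   identical corpus.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_users_en = 2000,
                         n_users_ja = 1000,
                         n_months = 6,
                         origin = as.Date("2020-02-01"),
                         degree_exponent = 1.5,
                         n_seed_influencers_per_month = 10,
                         pro_fraction = 0.6,
                         homophily = 0.9,
                         n_urls = 500,
                         url_lang_en_fraction = 0.7,
                         youtube_fraction = 0.05,
                         ald_location = 0,
                         ald_scale = 0.5,
                         ald_asymmetry = 1.5,
                         crosslingual_share_prob = 0.3,
                         events_per_user_per_month = 5,
                         rng_seed = 1L) {
  cfg <- list(
    n_users_en = n_users_en, n_users_ja = n_users_ja, n_months = n_months,
    origin = as.Date(origin), degree_exponent = degree_exponent,
    n_seed_influencers_per_month = n_seed_influencers_per_month,
    pro_fraction = pro_fraction, homophily = homophily, n_urls = n_urls,
    url_lang_en_fraction = url_lang_en_fraction,
    youtube_fraction = youtube_fraction,
    ald_location = ald_location, ald_scale = ald_scale,
    ald_asymmetry = ald_asymmetry,
    crosslingual_share_prob = crosslingual_share_prob,
    events_per_user_per_month = events_per_user_per_month,
    rng_seed = as.integer(rng_seed)
  )
  probs <- c("pro_fraction", "homophily", "url_lang_en_fraction",
             "youtube_fraction", "crosslingual_share_prob")
  for (p in probs) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1) {
      rlang::abort(paste0("`", p, "` must be a probability in [0, 1]."))
    }
  }
  counts <- c("n_users_en", "n_users_ja", "n_months", "n_urls",
              "n_seed_influencers_per_month")
  for (p in counts) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0) {
      rlang::abort(paste0("`", p, "` must be a non-negative count."))
    }
  }
  if (cfg$ald_scale <= 0) rlang::abort("`ald_scale` must be > 0.")
  if (cfg$ald_asymmetry <= 0) rlang::abort("`ald_asymmetry` must be > 0.")
  if (cfg$degree_exponent <= 0) rlang::abort("`degree_exponent` must be > 0.")
  if (cfg$events_per_user_per_month > 0 &&
      cfg$n_users_en + cfg$n_users_ja == 0) {
    rlang::abort("positive event rate with zero users.")
  }
  structure(cfg, class = "synth_config")
}

placeholder_vocab <- c(
  "zinc", "study", "treatment", "doxycycline", "hydroxychloroquine",
  "avigan", "kitasato", "horse", "overseas", "symptoms", "medicine",
  "professor", "trial", "dose", "ivermectin", "covid"
)

round_away_from_zero <- function(x) {
  ifelse(x >= 0, ceiling(x), floor(x))
}

#' Generate a synthetic bilingual retweet corpus
#'
#' Produces a retweet-event table plus the ground truth every downstream
#' stage can be checked against. Users carry a true stance and a
#' heavy-tailed (Pareto) attractiveness weight; baseline retweets pick
#' their source same-stance with probability `homophily`, otherwise from
#' the whole community, always proportionally to attractiveness. Each URL
#' gets a language, a native first-post day, and — with probability
#' `crosslingual_share_prob` — an adoption day in the other community
#' offset by a whole-day asymmetric Laplace draw (rounded away from zero,
#' so the sign of every lead/lag is preserved and the configured negative
#' mass equals the closed-form CDF mass below zero). Daily retweet counts
#' of a URL decay geometrically after each community's first post, so the
#' peak day coincides with the first-post day.
#'
#' @param config a [synth_config()] object.
#' @return A list with elements
#'   * `events` — retweet-event tibble (see [retweet-events]),
#'   * `ground_truth` — list of tibbles `users` (`user`, `community`,
#'     `stance`, `attractiveness`), `urls` (`canonical`, `language`,
#'     `is_youtube`, `native_day`, `cross`, `offset`, `nonnative_day`),
#'     and `seeds` (`user`, `stance`, `month`),
#'   * `config` — the configuration used.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(config$rng_seed)

  users <- synth_users(config)
  month_starts <- seq(config$origin, by = "month",
                      length.out = config$n_months + 1)
  base <- synth_baseline_events(config, users, month_starts)
  urls <- synth_urls(config, month_starts)
  url_ev <- synth_url_events(config, users, urls, month_starts)

  events <- dplyr::bind_rows(base, url_ev) |>
    dplyr::arrange(.data$timestamp) |>
    dplyr::mutate(event_id = sprintf("ev%08d", dplyr::row_number()),
                  .before = 1)

  seeds <- synth_seeds(config, users, month_starts)

  list(events = events,
       ground_truth = list(users = users, urls = urls, seeds = seeds),
       config = config)
}

synth_users <- function(config) {
  n <- c(en = config$n_users_en, ja = config$n_users_ja)
  purrr::map(c("en", "ja"), function(cm) {
    nc <- n[[cm]]
    if (nc == 0) return(NULL)
    tibble::tibble(
      user = sprintf("%s_u%05d", cm, seq_len(nc)),
      community = cm,
      stance = ifelse(stats::runif(nc) < config$pro_fraction,
                      "pro_use", "anti_use"),
      # Pareto(1, alpha): heavy-tailed influencer attractiveness
      attractiveness = stats::runif(nc)^(-1 / config$degree_exponent)
    )
  }) |>
    dplyr::bind_rows()
}

synth_baseline_events <- function(config, users, month_starts) {
  if (config$events_per_user_per_month == 0 || nrow(users) == 0) {
    return(empty_events()[, setdiff(event_columns, "event_id")])
  }
  purrr::map(c("en", "ja"), function(cm) {
    comm <- users[users$community == cm, ]
    if (nrow(comm) == 0) return(NULL)
    w <- comm$attractiveness
    idx_pro <- which(comm$stance == "pro_use")
    idx_anti <- which(comm$stance == "anti_use")
    purrr::map(seq_len(config$n_months), function(m) {
      t0 <- as.POSIXct(month_starts[m], tz = "UTC")
      t1 <- as.POSIXct(month_starts[m + 1], tz = "UTC")
      n_ev <- stats::rpois(1, config$events_per_user_per_month * nrow(comm))
      if (n_ev == 0) return(NULL)
      rt <- sample.int(nrow(comm), n_ev, replace = TRUE)
      same <- stats::runif(n_ev) < config$homophily
      src <- integer(n_ev)
      pick <- function(rows, pool) {
        if (length(rows) == 0) return()
        if (length(pool) == 0) pool <- seq_len(nrow(comm))
        src[rows] <<- pool[sample.int(length(pool), length(rows),
                                      replace = TRUE, prob = w[pool])]
      }
      pick(which(same & comm$stance[rt] == "pro_use"), idx_pro)
      pick(which(same & comm$stance[rt] == "anti_use"), idx_anti)
      pick(which(!same), seq_len(nrow(comm)))
      tibble::tibble(
        timestamp = t0 + stats::runif(n_ev) * as.numeric(difftime(t1, t0, units = "secs")),
        retweeter_id = comm$user[rt],
        source_user_id = comm$user[src],
        stream_language = cm,
        text = synth_text(n_ev),
        urls = rep(list(character(0)), n_ev)
      )
    }) |>
      dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()
}

synth_text <- function(n, k = 3) {
  m <- matrix(sample(placeholder_vocab, n * k, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = " ")
}

synth_urls <- function(config, month_starts) {
  n <- config$n_urls
  if (n == 0) {
    return(tibble::tibble(canonical = character(0), language = character(0),
                          is_youtube = logical(0), native_day = integer(0),
                          cross = logical(0), offset = integer(0),
                          nonnative_day = integer(0)))
  }
  total_days <- as.integer(month_starts[length(month_starts)] - month_starts[1])
  lang <- ifelse(stats::runif(n) < config$url_lang_en_fraction, "en", "ja")
  yt <- stats::runif(n) < config$youtube_fraction
  canonical <- ifelse(
    yt,
    # Japanese-content YouTube links carry a Japanese path token so that
    # string-based language tagging agrees with the ground truth
    ifelse(lang == "ja",
           sprintf("https://www.youtube.com/watch?v=%05dビ", seq_len(n)),
           sprintf("https://www.youtube.com/watch?v=vid%05d", seq_len(n))),
    ifelse(lang == "ja",
           sprintf("https://site%04d.example.jp/article/%05d", seq_len(n), seq_len(n)),
           sprintf("https://site%04d.example.com/article/%05d", seq_len(n), seq_len(n)))
  )
  native_day <- sample.int(total_days, n, replace = TRUE) - 1L
  cross <- stats::runif(n) < config$crosslingual_share_prob
  offset <- as.integer(round_away_from_zero(
    rald(n, config$ald_location, config$ald_scale, config$ald_asymmetry)))
  offset[!cross] <- NA_integer_
  tibble::tibble(
    canonical = canonical, language = lang, is_youtube = yt,
    native_day = native_day, cross = cross, offset = offset,
    nonnative_day = native_day + offset
  )
}

# daily retweet counts decaying geometrically after the first post
synth_daily_counts <- function(n0, ratio = 0.6) {
  counts <- integer(0)
  t <- 0
  repeat {
    ct <- floor(n0 * ratio^t)
    if (ct < 1) break
    counts <- c(counts, ct)
    t <- t + 1
  }
  if (length(counts) == 0) counts <- 1L
  counts
}

synth_url_events <- function(config, users, urls, month_starts) {
  if (nrow(urls) == 0 || nrow(users) == 0) {
    return(empty_events()[, setdiff(event_columns, "event_id")])
  }
  origin <- month_starts[1]
  pro <- users[users$stance == "pro_use", ]
  out <- purrr::map(c("en", "ja"), function(cm) {
    comm <- pro[pro$community == cm, ]
    if (nrow(comm) == 0) return(NULL)
    native <- urls[urls$language == cm, ]
    adopted <- urls[urls$language != cm & urls$cross, ]
    spans <- dplyr::bind_rows(
      tibble::tibble(canonical = native$canonical, day0 = native$native_day),
      tibble::tibble(canonical = adopted$canonical, day0 = adopted$nonnative_day)
    )
    if (nrow(spans) == 0) return(NULL)
    # one fixed poster per URL and community, drawn by attractiveness
    posters <- comm$user[sample.int(nrow(comm), nrow(spans), replace = TRUE,
                                    prob = comm$attractiveness)]
    n0 <- 1L + stats::rpois(nrow(spans), 3)
    purrr::map(seq_len(nrow(spans)), function(i) {
      counts <- synth_daily_counts(n0[i])
      days <- rep(spans$day0[i] + seq_along(counts) - 1L, counts)
      n_ev <- length(days)
      rt <- comm$user[sample.int(nrow(comm), n_ev, replace = TRUE)]
      tibble::tibble(
        timestamp = as.POSIXct(origin, tz = "UTC") + days * 86400 +
          stats::runif(n_ev, 0, 86399),
        retweeter_id = rt,
        source_user_id = posters[i],
        stream_language = cm,
        text = synth_text(n_ev),
        urls = as.list(rep(spans$canonical[i], n_ev))
      )
    }) |>
      dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()
  out
}

synth_seeds <- function(config, users, month_starts) {
  k <- config$n_seed_influencers_per_month
  if (k == 0 || nrow(users) == 0) {
    return(tibble::tibble(user = character(0), stance = character(0),
                          month = character(0)))
  }
  months <- format(month_starts[seq_len(config$n_months)], "%Y-%m")
  top <- users |>
    dplyr::group_by(.data$community, .data$stance) |>
    dplyr::arrange(dplyr::desc(.data$attractiveness), .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup()
  tidyr::expand_grid(month = months,
                     top[, c("user", "stance", "community")]) |>
    dplyr::arrange(.data$month, .data$user)
}

#' Write a synthetic corpus to disk
#'
#' Writes the event file (JSONL), ground-truth CSVs, the configuration
#' (JSON) and a manifest with the seed, a configuration hash and row
#' counts. The fixture round-trips through [read_events()].
#'
#' @param corpus output of [generate_corpus()].
#' @param dir writable output directory (created if absent).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_fixture <- function(corpus, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(paste0("cannot create directory: ", dir))
  }
  paths <- c(
    events = file.path(dir, "events.jsonl"),
    users = file.path(dir, "users.csv"),
    urls = file.path(dir, "urls.csv"),
    seeds = file.path(dir, "seeds.csv"),
    config = file.path(dir, "config.json"),
    manifest = file.path(dir, "manifest.json")
  )
  write_events(corpus$events, paths[["events"]])
  readr::write_csv(corpus$ground_truth$users, paths[["users"]], progress = FALSE)
  readr::write_csv(corpus$ground_truth$urls, paths[["urls"]], progress = FALSE)
  readr::write_csv(corpus$ground_truth$seeds, paths[["seeds"]], progress = FALSE)
  cfg <- unclass(corpus$config)
  cfg$origin <- as.character(cfg$origin)
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = corpus$config$rng_seed,
    config_hash = rlang::hash(cfg),
    n_events = nrow(corpus$events),
    n_users = nrow(corpus$ground_truth$users),
    n_urls = nrow(corpus$ground_truth$urls),
    n_seed_rows = nrow(corpus$ground_truth$seeds)
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
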