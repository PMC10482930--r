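day_ts <- function(day, sec = 0) {
  as.POSIXct("2021-01-01", tz = "UTC") + day * 86400 + sec
}

# two communities sharing one URL; en leads ja by 2 days on url1
fixture_events <- function() {
  make_events(
    retweeter = c("e1", "e2", "e2", "j1", "j2", "j1", "e1", "j1"),
    source = rep("S", 8),
    timestamp = c(day_ts(10), day_ts(11), day_ts(11, 60), day_ts(12),
                  day_ts(12, 60), day_ts(13), day_ts(5), day_ts(6)),
    stream = c("en", "en", "en", "ja", "ja", "ja", "en", "ja"),
    urls = list("https://news.example.com/a", "https://news.example.com/a",
                "https://news.example.com/a", "https://news.example.com/a",
                "https://news.example.com/a", "https://news.example.com/a",
                "https://other.example.com/b", "https://site.example.jp/c")
  )
}

fixture_labels <- function(stance_j2 = "pro_use") {
  tibble::tibble(
    user = c("e1", "e2", "j1", "j2", "S"),
    stance = c("pro_use", "pro_use", "pro_use", stance_j2, "pro_use")
  )
}

fixture_langmap <- function() {
  tibble::tibble(user = c("e1", "e2", "j1", "j2", "S"),
                 native_language = c("en", "en", "ja", "ja", "en"))
}

test_that("URL language detection: overrides beat detectors beat heuristic", {
  urls <- c("https://www.dailyshincho.jp/article/2021", "https://www.reuters.com/aticle/x")
  expect_equal(detect_url_language(urls), c("ja", "en"))
  # Japanese characters anywhere in the URL
  expect_equal(detect_url_language("https://www.youtube.com/watch?v=ビ123"), "ja")
  # detector wins over heuristic
  expect_equal(detect_url_language(urls[2], detector = function(u) "ja"), "ja")
  # unknown detector output maps to other
  expect_equal(detect_url_language(urls[2], detector = function(u) "de"), "other")
  # override wins over everything
  ov <- c("https://www.reuters.com/aticle/x" = "ja")
  expect_equal(detect_url_language(urls[2], detector = function(u) "en",
                                   overrides = ov), "ja")
})

test_that("URL records count pro-use events per community with daily series", {
  recs <- build_url_records(fixture_events(), fixture_labels(),
                            fixture_langmap())
  a <- recs[recs$canonical == "https://news.example.com/a", ]
  expect_equal(a$retweets_en, 3L)
  expect_equal(a$retweets_ja, 3L)
  expect_true(a$shared)
  expect_equal(a$first_post_day_en, as.Date("2021-01-11"))
  expect_equal(a$first_post_day_ja, as.Date("2021-01-13"))
  expect_equal(a$url_language, "en")
  daily <- a$daily[[1]]
  expect_equal(sum(daily$n[daily$community == "en"]), a$retweets_en)
  expect_equal(min(daily$day[daily$community == "ja"]), a$first_post_day_ja)

  b <- recs[recs$canonical == "https://other.example.com/b", ]
  expect_false(b$shared)
  expect_equal(b$retweets_ja, 0L)
})

test_that("URLs retweeted only by anti-use users are excluded", {
  labels <- tibble::tibble(user = c("e1", "e2", "j1", "j2"),
                           stance = c("anti_use", "anti_use", "pro_use",
                                      "pro_use"))
  recs <- build_url_records(fixture_events(), labels, fixture_langmap())
  expect_false("https://other.example.com/b" %in% recs$canonical)  # only e1
  a <- recs[recs$canonical == "https://news.example.com/a", ]
  expect_equal(a$retweets_en, 0L)
})

test_that("per-URL counts conserve the pro-use URL-bearing events", {
  corpus <- generate_corpus(synth_config(n_users_en = 100, n_users_ja = 60,
                                         n_months = 2, n_urls = 80,
                                         events_per_user_per_month = 1,
                                         rng_seed = 14))
  gt <- corpus$ground_truth$users
  labels <- tibble::tibble(user = gt$user, stance = gt$stance)
  langmap <- tibble::tibble(user = gt$user, native_language = gt$community)
  recs <- build_url_records(corpus$events, labels, langmap)
  pro <- gt$user[gt$stance == "pro_use"]
  n_expected <- sum(corpus$events$retweeter_id %in% pro &
                      purrr::map_int(corpus$events$urls, length) > 0)
  expect_equal(sum(recs$retweets_en) + sum(recs$retweets_ja), n_expected)
})

test_that("non-native sharing counts distinct URLs only", {
  # j1 shares 3 distinct en URLs (one twice); e1 shares only native URLs
  ev <- make_events(
    retweeter = c("j1", "j1", "j1", "j1", "e1"),
    source = rep("S", 5),
    stream = c("ja", "ja", "ja", "ja", "en"),
    urls = list("https://a.example.com/1", "https://a.example.com/1",
                "https://b.example.com/2", "https://c.example.com/3",
                "https://d.example.com/4")
  )
  labels <- tibble::tibble(user = c("j1", "e1", "S"), stance = "pro_use")
  langmap <- tibble::tibble(user = c("j1", "e1", "S"),
                            native_language = c("ja", "en", "en"))
  recs <- build_url_records(ev, labels, langmap)
  deg <- build_degree_table(ev)
  rk <- nonnative_share_ranking(recs, ev, labels, langmap, deg, top_n = 10)
  expect_equal(rk$n_unique_nonnative_urls[rk$user == "j1"], 3L)
  expect_equal(rk$n_unique_nonnative_urls[rk$user == "e1"], 0L)  # native-only
})

test_that("ja users given higher cross-lingual adoption out-share en users", {
  # en-language URLs dominate the cross-lingual pool, so ja users adopt
  # non-native URLs far more often than en users, as in the study system
  corpus <- generate_corpus(synth_config(n_users_en = 300, n_users_ja = 150,
                                         n_months = 3, n_urls = 400,
                                         url_lang_en_fraction = 0.8,
                                         crosslingual_share_prob = 0.5,
                                         events_per_user_per_month = 1,
                                         rng_seed = 23))
  gt <- corpus$ground_truth$users
  labels <- tibble::tibble(user = gt$user, stance = gt$stance)
  langmap <- tibble::tibble(user = gt$user, native_language = gt$community)
  recs <- build_url_records(corpus$events, labels, langmap)
  deg <- build_degree_table(corpus$events)
  rk <- nonnative_share_ranking(recs, corpus$events, labels, langmap, deg,
                                top_n = 100)
  means <- tapply(rk$n_unique_nonnative_urls, rk$native_language, mean)
  expect_gt(means[["ja"]], means[["en"]])
})

test_that("spline smoothing honours its contracts", {
  x <- c(5, 1, 4, 2, 6, 3, 7, 2, 8, 4)
  expect_equal(smooth_series(x, smoothing = 0), x)
  expect_equal(smooth_series(rep(3, 10), smoothing = 0.1), rep(3, 10))
  expect_warning(out <- smooth_series(c(1, 2, 3), smoothing = 0.1), "4 points")
  expect_equal(out, c(1, 2, 3))

  set.seed(4)
  noisy <- sort(stats::runif(50, 0, 10)) + stats::rnorm(50, 0, 0.5)
  sm <- smooth_series(noisy, smoothing = 1e-2)
  expect_lt(sum(abs(diff(sm))), sum(abs(diff(noisy))))  # reduced variation
  expect_true(all(sm >= min(noisy) - 1e-6 & sm <= max(noisy) + 1e-6))
})

test_that("timing observations compute first and peak day differences", {
  recs <- build_url_records(fixture_events(), fixture_labels(),
                            fixture_langmap())
  obs <- timing_observations(recs)
  a <- obs[obs$canonical == "https://news.example.com/a", ]
  expect_equal(a$direction, "en_url_adopted_by_ja")
  expect_equal(a$day_diff_first, 2L)   # ja first post day 12 vs en day 10
  # ja daily series: day12 -> 2 retweets, day13 -> 1; peak (earliest max) day 12
  expect_equal(a$day_diff_peak, 2L)
  # unshared URLs are skipped
  expect_false("https://other.example.com/b" %in% obs$canonical)
})

test_that("a non-native lead produces a negative first-post difference", {
  ev <- make_events(
    retweeter = c("j1", "e1"), source = c("S", "S"),
    timestamp = c(day_ts(8), day_ts(10)),
    stream = c("ja", "en"),
    urls = list("https://lead.example.com/x", "https://lead.example.com/x")
  )
  recs <- build_url_records(ev, fixture_labels(), fixture_langmap())
  obs <- timing_observations(recs)
  expect_equal(obs$day_diff_first, -2L)  # native en first post day 10, ja day 8
})

test_that("peak-day ties break to the earliest day", {
  # non-native series {10: 2, 11: 5, 12: 5}; day 0 = 10
  ev <- make_events(
    retweeter = c("e1", rep("j1", 6), rep("j2", 6)),
    source = rep("S", 13),
    timestamp = c(day_ts(10), day_ts(10), day_ts(10, 60),
                  day_ts(11), day_ts(11, 1), day_ts(11, 2),
                  day_ts(11, 3), day_ts(11, 4),
                  day_ts(12), day_ts(12, 1), day_ts(12, 2), day_ts(12, 3),
                  day_ts(12, 4)),
    stream = c("en", rep("ja", 12)),
    urls = rep(list("https://tie.example.com/x"), 13)
  )
  recs <- build_url_records(ev, fixture_labels(), fixture_langmap())
  obs <- timing_observations(recs)
  expect_equal(obs$day_diff_peak, 1L)
})

test_that("the YouTube flag drops all YouTube-host URLs", {
  ev <- make_events(
    retweeter = c("e1", "j1", "e2", "j2"),
    source = rep("S", 4),
    timestamp = c(day_ts(1), day_ts(2), day_ts(3), day_ts(4)),
    stream = c("en", "ja", "en", "ja"),
    urls = list("https://youtu.be/abc", "https://youtu.be/abc",
                "https://news.example.com/a", "https://news.example.com/a")
  )
  recs <- build_url_records(ev, fixture_labels(), fixture_langmap())
  with_yt <- timing_observations(recs, youtube_excluded = FALSE)
  without <- timing_observations(recs, youtube_excluded = TRUE)
  expect_equal(nrow(with_yt), 2)
  expect_equal(nrow(without), 1)
  expect_false(any(grepl("youtu", without$canonical)))
})

test_that("timing is invariant to a uniform time translation", {
  shift_events <- function(ev, days) {
    dplyr::mutate(ev, timestamp = timestamp + days * 86400)
  }
  recs0 <- build_url_records(fixture_events(), fixture_labels(),
                             fixture_langmap())
  recs7 <- build_url_records(shift_events(fixture_events(), 7),
                             fixture_labels(), fixture_langmap())
  obs0 <- timing_observations(recs0)
  obs7 <- timing_observations(recs7)
  expect_equal(obs0$day_diff_first, obs7$day_diff_first)
  expect_equal(obs0$day_diff_peak, obs7$day_diff_peak)
})
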