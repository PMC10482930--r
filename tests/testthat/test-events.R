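test_that("JSONL events round-trip with all field values preserved", {
  ev <- make_events(c("u1", "u2", "u3"), c("A", "A", "B"),
                    text = "some text",
                    urls = list(character(0), "https://example.com/a",
                                c("https://x.test/1", "https://y.test/2")))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back, ev)
})

test_that("CSV events round-trip, urls pipe-delimited", {
  ev <- make_events(c("u1", "u2"), c("A", "B"), stream = c("en", "ja"),
                    text = c("hello", "world"),
                    urls = list(c("https://x.test/1", "https://y.test/2"),
                                character(0)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back, ev)
})

test_that("empty input gives an empty event table, not an error", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), path)
  ev <- read_events(path)
  expect_equal(nrow(ev), 0)
  expect_setequal(names(ev), c("event_id", "timestamp", "retweeter_id",
                               "source_user_id", "stream_language", "text",
                               "urls"))
})

test_that("malformed records fail hard, naming the field and line", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  ok <- '{"event_id":"e1","timestamp":"2021-06-01T00:00:00Z","retweeter_id":"u1","source_user_id":"A","stream_language":"en","text":"x","urls":[]}'
  bad <- '{"event_id":"e2","timestamp":"2021-06-01T00:00:00Z","retweeter_id":"u2","stream_language":"en","text":"x","urls":[]}'
  writeLines(c(ok, bad), path)
  expect_error(read_events(path), "line 2.*source_user_id")

  writeLines(c(sub("2021-06-01T00:00:00Z", "not-a-time", ok)), path)
  expect_error(read_events(path), "timestamp")

  writeLines(c(sub('"stream_language":"en"', '"stream_language":"fr"', ok)), path)
  expect_error(read_events(path), "stream_language")
})

test_that("native language follows stream, majority, then tie rules", {
  # single-stream user, majority user, and a 2-2 tie whose earliest event is ja
  ts <- as.POSIXct("2021-06-01", tz = "UTC") + c(5, 1, 2, 3, 4, 0, 6, 7, 8) * 3600
  ev <- make_events(
    retweeter = c("solo", "maj", "maj", "maj", "maj", "tie", "tie", "tie", "tie"),
    source = rep("Z", 9),
    timestamp = ts,
    stream = c("ja", "en", "en", "en", "ja", "ja", "en", "ja", "en")
  )
  map <- assign_native_language(ev)
  lang <- stats::setNames(map$native_language, map$user)
  expect_equal(unname(lang["solo"]), "ja")
  expect_equal(unname(lang["maj"]), "en")
  expect_equal(unname(lang["tie"]), "ja")   # tie broken by earliest event
  # source-only users are covered too
  expect_true("Z" %in% map$user)
})

test_that("a timestamp tie on a dual-stream split resolves to en", {
  ts <- rep(as.POSIXct("2021-06-01", tz = "UTC"), 2)
  ev <- make_events(c("u", "u"), c("A", "B"), timestamp = ts,
                    stream = c("ja", "en"))
  map <- assign_native_language(ev)
  expect_equal(map$native_language[map$user == "u"], "en")
})

test_that("month partition respects UTC boundaries and conserves events", {
  ts <- as.POSIXct(c("2021-08-31 23:59:00", "2021-09-01 00:00:00"), tz = "UTC")
  ev <- make_events(c("u1", "u2"), c("A", "B"), timestamp = ts)
  parts <- partition_by_month(ev)
  expect_equal(names(parts), c("2021-08", "2021-09"))
  expect_equal(sum(vapply(parts, nrow, integer(1))), nrow(ev))

  # conservation on a generated corpus
  corpus <- generate_corpus(synth_config(n_users_en = 60, n_users_ja = 30,
                                         n_months = 3, n_urls = 40,
                                         rng_seed = 5))
  parts <- partition_by_month(corpus$events)
  expect_equal(sum(vapply(parts, nrow, integer(1))), nrow(corpus$events))
  expect_equal(sort(unname(unlist(purrr::map(parts, "event_id")))),
               sort(corpus$events$event_id))
})

test_that("URL normalisation applies the documented rules", {
  res <- normalize_url("HTTPS://Example.com/a/?utm_source=x#frag")
  expect_equal(res$canonical, "https://example.com/a")
  expect_false(res$is_youtube)

  expect_true(normalize_url("https://youtu.be/abc")$is_youtube)
  expect_true(normalize_url("https://m.youtube.com/watch?v=1")$is_youtube)

  kept <- normalize_url("https://example.com/a?page=2&utm_medium=z&b=1")
  expect_equal(kept$canonical, "https://example.com/a?page=2&b=1")

  bad <- normalize_url("not a url")
  expect_false(bad$valid)
  expect_true(is.na(bad$canonical))

  # scheme-less URLs (as printed in the wild) are assumed https
  expect_equal(normalize_url("example.com/x")$canonical, "https://example.com/x")
})

test_that("URL normalisation is idempotent on fuzzed inputs", {
  set.seed(99)
  schemes <- c("http://", "HTTPS://", "", "ftp://")
  hosts <- c("Example.com", "news.site.jp", "youtu.be", "a-b.c0.org")
  paths <- c("", "/", "/a", "/a/", "/a/b.html", "/a%20b")
  queries <- c("", "?utm_source=x", "?page=2", "?b=1&utm_campaign=z&a=2",
               "?fbclid=123")
  frags <- c("", "#x", "#frag/2")
  raw <- paste0(sample(schemes, 1000, TRUE), sample(hosts, 1000, TRUE),
                sample(paths, 1000, TRUE), sample(queries, 1000, TRUE),
                sample(frags, 1000, TRUE))
  first <- normalize_url(raw)
  second <- normalize_url(first$canonical[first$valid])
  expect_equal(second$canonical, first$canonical[first$valid])
  expect_equal(second$is_youtube, first$is_youtube[first$valid])
})
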