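test_that("read_matches parses, sorts and validates CSV input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "match_id,gamer_id,started_at,finished_at,kills,deaths,assists",
    "m2,g1,2021-03-01T21:00:00Z,2021-03-01T21:40:00Z,15,12,3",
    "m1,g1,2021-03-01T20:00:00Z,2021-03-01T20:38:00Z,20,14,5"
  ), path)
  m <- read_matches(path)
  expect_equal(m$match_id, c("m1", "m2")) # sorted by started_at
  expect_s3_class(m$started_at, "POSIXct")
  expect_equal(attr(m$started_at, "tzone"), "UTC")
  expect_equal(m$duration_min, c(38, 40))

  # header-only file -> empty, typed collection
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("match_id,gamer_id,started_at,finished_at,kills,deaths,assists", empty)
  e <- read_matches(empty)
  expect_equal(nrow(e), 0)
  expect_s3_class(e$started_at, "POSIXct")
})

test_that("read_matches rejects invalid rows with informative errors", {
  bad_span <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "match_id,gamer_id,started_at,finished_at,kills,deaths,assists",
    "mX,g1,2021-03-01T21:00:00Z,2021-03-01T20:40:00Z,1,1,1"
  ), bad_span)
  expect_error(read_matches(bad_span), "mX")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "match_id,gamer_id,started_at,finished_at,kills,deaths,assists",
    "m1,g1,2021-03-01T10:00:00Z,2021-03-01T10:40:00Z,1,1,1",
    "m1,g1,2021-03-01T12:00:00Z,2021-03-01T12:40:00Z,1,1,1"
  ), dup)
  expect_error(read_matches(dup), "Duplicate match_id")

  bad_ts <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "match_id,gamer_id,started_at,finished_at,kills,deaths,assists",
    "m1,g1,not-a-time,2021-03-01T10:40:00Z,1,1,1"
  ), bad_ts)
  expect_error(read_matches(bad_ts), "Malformed started_at")
})

test_that("match histories round-trip through CSV and JSONL", {
  set.seed(42)
  m <- random_history(12)
  for (ext in c(".csv", ".jsonl")) {
    path <- withr::local_tempfile(fileext = ext)
    write_matches(m, path)
    back <- read_matches(path)
    expect_equal(back$match_id, m$match_id)
    expect_equal(back$started_at, m$started_at)
    expect_equal(back$finished_at, m$finished_at)
    expect_equal(back$kills, m$kills)
  }
})

test_that("emotion streams are normalized to sum to 100 and validated", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "stream_id,t,angry,disgust,fear,happy,sad,surprise,neutral",
    "v1,0,50,0,0,50,0,0,0",
    "v1,1,1,1,1,1,1,1,1",
    "v1,3,2,0,0,2,0,0,0"
  ), path)
  f <- read_emotion_stream(path)
  expect_equal(as.numeric(f[1, c("angry", "happy")]), c(50, 50)) # already normalized
  expect_equal(as.numeric(f[2, emotion_channels()]), rep(100 / 7, 7)) # symmetry
  expect_true(all(abs(rowSums(f[, emotion_channels()]) - 100) < 1e-6))
  # the missing second t = 2 is recorded
  expect_equal(attr(f, "gaps")$n_missing_seconds, 1L)

  zero <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "stream_id,t,angry,disgust,fear,happy,sad,surprise,neutral",
    "v1,0,0,0,0,0,0,0,0"
  ), zero)
  expect_error(read_emotion_stream(zero), "All-zero")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "stream_id,t,angry,disgust,fear,happy,sad,surprise,neutral",
    "v1,0,-5,10,10,10,10,10,55"
  ), neg)
  expect_error(read_emotion_stream(neg), "Negative")
})

test_that("generated inputs round-trip through their writers and readers", {
  set.seed(7)
  withr::local_seed(7)
  h <- generate_history(gamer_profile("amateur", seed = 7), "2024-01-01", "2024-01-21")
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_matches(h$matches, p1)
  expect_equal(read_matches(p1)$started_at, h$matches$started_at)

  ev <- generate_events(600, n_kills = 3, n_deaths = 3, seed = 1)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, p2)
  expect_equal(read_events(p2), ev)

  emo <- generate_emotion_stream(emotion_profile(seed = 2), 120, stream_id = "v1")
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_emotion_stream(emo, p3)
  back <- read_emotion_stream(p3)
  expect_equal(as.data.frame(back[, emotion_channels()]),
               as.data.frame(emo[, emotion_channels()]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("reports round-trip losslessly and writes are byte-identical", {
  set.seed(11)
  m <- sessionize(random_history(30), 30)
  hs <- historical_stats(m, "2023-01-01", "2023-12-31")
  rs <- recent_stats(m, as.Date("2023-02-01"))
  pe <- period_emotion_average(random_frames(50))

  for (rep in list(hs, rs, pe)) {
    p <- withr::local_tempfile(fileext = ".json")
    write_report(rep, p)
    expect_equal(read_report(p), rep, ignore_attr = FALSE)
    p2 <- withr::local_tempfile(fileext = ".json")
    write_report(rep, p2)
    expect_identical(readBin(p, "raw", file.size(p)), readBin(p2, "raw", file.size(p2)))
  }
})

test_that("empty report blocks serialize as explicit nulls, not missing keys", {
  empty <- sessionize(make_matches(character(0), numeric(0)), 30)
  hs <- historical_stats(empty, "2023-01-01", "2023-01-31")
  p <- withr::local_tempfile(fileext = ".json")
  write_report(hs, p)
  parsed <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  expect_true("avg_matches_per_session" %in% names(parsed$body$session_stats))
  expect_null(parsed$body$session_stats$avg_matches_per_session)
  expect_equal(parsed$body$general$n_matches, 0L)
  back <- read_report(p)
  expect_true(is.na(back$session_stats$avg_matches_per_session))
})
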