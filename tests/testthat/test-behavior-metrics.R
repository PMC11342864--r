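test_that("percent_difference rounds half away from zero and guards its domain", {
  expect_equal(percent_difference(10, 10), 0L)
  expect_equal(percent_difference(15, 10), 50L)
  expect_true(is.na(percent_difference(3, 0)))
  expect_error(percent_difference(-1, 10), "nonnegative")
  # half-away rounding, both signs: 2.5% -> 3, -2.5% -> -3
  expect_equal(percent_difference(205, 200), 3L)
  expect_equal(percent_difference(195, 200), -3L)
})

test_that("a single 40-minute match concentrates every historical block", {
  m <- sessionize(make_matches("2021-03-06 15:00:00", 40), 30) # Saturday afternoon
  hs <- historical_stats(m, "2021-03-01", "2021-03-31")
  expect_equal(hs$general$n_matches, 1L)
  expect_equal(hs$general$total_hours_played, 40 / 60, tolerance = 1e-9)
  expect_equal(hs$general$total_hours_connected, 40 / 60, tolerance = 1e-9)
  expect_equal(hs$session_stats$avg_matches_per_session, 1)
  expect_equal(hs$day_part$matches_fraction$afternoon, 1)
  expect_equal(hs$day_part$matches_fraction$morning, 0)
  expect_equal(hs$weekday$matches_fraction$weekend, 1)
  expect_equal(hs$day_part$avg_daily_hours$afternoon, (40 / 60) / 31, tolerance = 1e-9)
})

test_that("monthly averages divide by active months only", {
  # 320 matches spread over exactly 10 distinct months -> monthly avg 32
  starts <- character(0)
  months <- c(1, 2, 3, 4, 5, 7, 9, 10, 11, 12) # June and August inactive
  for (i in 0:319) {
    mth <- months[(i %% 10) + 1]
    day <- 1 + (i %/% 10) %% 27
    starts <- c(starts, sprintf("2021-%02d-%02d 16:00:00", mth, day))
  }
  m <- make_matches(sort(starts), 40, ids = sprintf("m%04d", 1:320))
  hs <- historical_stats(sessionize(m, 30), "2021-01-01", "2021-12-31")
  expect_equal(hs$monthly$n_active_months, 10L)
  expect_equal(hs$monthly$avg_matches, 32)
  # brute-force the active-month count independently
  expect_equal(length(unique(format(as.Date(m$started_at), "%Y-%m"))), 10)
})

test_that("historical fractions conserve match counts and hours order correctly", {
  set.seed(31)
  for (i in 1:25) {
    h <- generate_history(
      gamer_profile(sample(c("amateur", "professional"), 1), off_months = integer(0), seed = i),
      "2024-01-01", "2024-02-25", seed = i
    )
    if (nrow(h$matches) == 0) next
    m <- sessionize(h$matches, 30)
    hs <- historical_stats(m, "2024-01-01", "2024-02-25")
    dp <- unlist(hs$day_part$matches_fraction)
    wd <- unlist(hs$weekday$matches_fraction)
    expect_equal(sum(dp), 1, tolerance = 1e-9)
    expect_equal(sum(wd), 1, tolerance = 1e-9)
    # conservation before rounding: fractions times n_matches are integers
    expect_equal(sum(round(dp * hs$general$n_matches)), hs$general$n_matches)
    expect_true(hs$general$total_hours_played <= hs$general$total_hours_connected + 1e-9)
    expect_true(hs$session_stats$avg_matches_per_session >= 1)
  }
})

test_that("played hours ignore the session partition; connected hours shrink with the threshold", {
  set.seed(8)
  m <- random_history(60)
  played <- function(th) {
    historical_stats(sessionize(m, th), "2023-01-01", "2023-12-31")$general$total_hours_played
  }
  connected <- function(th) {
    historical_stats(sessionize(m, th), "2023-01-01", "2023-12-31")$general$total_hours_connected
  }
  thr <- c(90, 60, 30, 10, 0)
  expect_true(all(abs(vapply(thr, played, numeric(1)) - played(30)) < 1e-9))
  expect_true(all(diff(vapply(thr, connected, numeric(1))) <= 1e-9))
})

test_that("recent_stats handles empty and periodic histories", {
  empty <- sessionize(make_matches(character(0), numeric(0)), 30)
  rs <- recent_stats(empty, as.Date("2023-06-01"))
  expect_equal(rs$total_hours_last_7d, 0)
  expect_true(is.na(rs$pct_diff_hours_vs_prev_week))
  expect_true(is.na(rs$hours_per_session_last_7d))
  expect_equal(nrow(rs$daily_series), 13)

  # same weekly schedule repeated for 6 weeks -> all differences are 0
  starts <- as.POSIXct(character(0))
  for (w in 0:5) {
    base <- utc("2023-04-03 18:00:00") + w * 7 * 86400
    starts <- c(starts, base, base + 2 * 86400 + 3600)
  }
  m <- sessionize(make_matches(format(sort(starts), "%Y-%m-%d %H:%M:%S"), 45,
                               ids = sprintf("m%03d", seq_along(starts))), 30)
  rs2 <- recent_stats(m, as.Date("2023-05-15"))
  expect_equal(rs2$pct_diff_hours_vs_prev_week, 0L)
  expect_equal(rs2$pct_diff_hps_vs_prev_week, 0L)
  expect_equal(rs2$pct_diff_hours_vs_prev_month, 0L)
})

test_that("recent_stats matches hand-computed values on a planted history", {
  # 10 h played in the last week, 8 h in the week before -> +25 %
  mk <- function(day_offsets, hours_each, id0) {
    starts <- utc("2023-06-12 00:00:00") + day_offsets * 86400 + 10 * 3600
    make_matches(format(starts, "%Y-%m-%d %H:%M:%S"), hours_each * 60,
                 ids = sprintf("m%02d", id0 + seq_along(starts)))
  }
  m <- dplyr::bind_rows(
    mk(c(-14, -13, -12, -9), 2, 0), # previous week: 8 h in 4 sessions
    mk(c(-7, -6, -5, -4, -2), 2, 10) # current week: 10 h in 5 sessions
  ) %>% dplyr::arrange(started_at)
  s <- sessionize(m, 30)
  rs <- recent_stats(s, as.POSIXct("2023-06-12 00:00:00", tz = "UTC"))
  expect_equal(rs$total_hours_last_7d, 10)
  expect_equal(rs$pct_diff_hours_vs_prev_week, 25L)
  expect_equal(rs$total_sessions_last_7d, 5L)
  expect_equal(rs$hours_per_session_last_7d, 2)
  # the 13-day series starts one day after the oldest (-14 d) match
  expect_equal(sum(rs$daily_series$n_matches), 8)
})

test_that("recent_stats is invariant under whole-day time shifts", {
  set.seed(77)
  h <- generate_history(gamer_profile("amateur", off_months = integer(0), seed = 3),
                        "2024-01-01", "2024-02-25", seed = 3)
  m <- sessionize(h$matches, 30)
  rs <- recent_stats(m, as.Date("2024-02-20"))
  k <- 11
  shifted <- m %>%
    dplyr::mutate(
      started_at = started_at + k * 86400,
      finished_at = finished_at + k * 86400
    )
  rs_shift <- recent_stats(shifted, as.Date("2024-02-20") + k)
  for (f in c(
    "total_hours_last_7d", "pct_diff_hours_vs_prev_week",
    "pct_diff_hours_vs_prev_month", "total_sessions_last_7d",
    "hours_per_session_last_7d", "pct_diff_hps_vs_prev_week",
    "pct_diff_hps_vs_prev_month"
  )) {
    expect_equal(rs_shift[[f]], rs[[f]], info = f)
  }
  expect_equal(rs_shift$daily_series$n_matches, rs$daily_series$n_matches)
  expect_equal(rs_shift$daily_series$day, rs$daily_series$day + k)
})

test_that("tidiers expose reports as tibbles", {
  set.seed(2)
  m <- sessionize(random_history(25), 30)
  hs <- historical_stats(m, "2023-01-01", "2023-12-31")
  td <- tidy(hs)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("block", "metric", "value") %in% names(td)))
  expect_equal(
    td$value[td$metric == "n_matches"], 25
  )
  gl <- glance(hs)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$avg_matches_per_session, hs$session_stats$avg_matches_per_session)

  rs <- recent_stats(m, as.Date("2023-02-01"))
  expect_equal(nrow(tidy(rs)), 7)
  expect_equal(nrow(glance(rs)), 1)
})
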