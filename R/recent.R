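#' Recent gaming-behavior metrics
#'
#' The between-consultation monitoring block: total played hours and session
#' intensity over the last 7 days, with signed percent differences against
#' the previous week and against a previous-month baseline, plus a 13-day
#' daily matches-vs-sessions series.
#'
#' Windows are anchored at `as_of` (exclusive): the current week is
#' `[as_of - 7d, as_of)`, the previous week `[as_of - 14d, as_of - 7d)`, and
#' the previous-month baseline is the mean weekly value over the four weeks
#' `[as_of - 35d, as_of - 7d)`. Played hours are attributed to the window in
#' which the match *started*; sessions belong to the window of their
#' `session_start` and are never split. `hours_per_session` divides the
#' connected hours of the window's sessions by their count and is `NA` when
#' no session started in the window; percent differences are `NA` when the
#' baseline is zero.
#'
#' @param matches A sessionized matches tibble (see [sessionize()]) for a
#'   single gamer.
#' @param as_of Anchor timestamp (POSIXct, or a `Date` taken as local
#'   midnight); windows end just before it.
#' @param tz Olson timezone for the daily-series calendar.
#' @param config A [gametel_config()]; embedded in the report.
#' @return An object of class `gametel_recent` with fields
#'   `total_hours_last_7d`, `pct_diff_hours_vs_prev_week`,
#'   `pct_diff_hours_vs_prev_month`, `total_sessions_last_7d`,
#'   `hours_per_session_last_7d`, `pct_diff_hps_vs_prev_week`,
#'   `pct_diff_hps_vs_prev_month`, and `daily_series` (13 rows, one per
#'   local calendar day ending at `as_of`).
#' @seealso [historical_stats()], [percent_difference()]
#' @export
recent_stats <- function(matches, as_of, tz = "UTC",
                         config = gametel_config(tz = tz)) {
  check_matches(matches)
  if (!"session_id" %in% names(matches)) {
    abort("`matches` has no `session_id`; call sessionize() first.")
  }
  if (inherits(as_of, "Date")) {
    as_of <- force_tz(as.POSIXct(paste(as_of, "00:00:00"), tz = tz), tz)
  }
  sess <- if (nrow(matches) > 0) session_summary(matches) else
    tibble(
      session_id = character(), n_matches = integer(),
      session_start = as.POSIXct(character(), tz = "UTC"),
      session_end = as.POSIXct(character(), tz = "UTC"),
      span_hours = numeric(), played_hours = numeric()
    )

  win_start <- function(days_back) as_of - days_back * 86400

  played_hours_in <- function(lo, hi) {
    sel <- matches$started_at >= lo & matches$started_at < hi
    sum(secs_between(matches$started_at[sel], matches$finished_at[sel])) / 3600
  }
  sessions_in <- function(lo, hi) {
    sess[sess$session_start >= lo & sess$session_start < hi, ]
  }
  hps <- function(s) if (nrow(s) > 0) sum(s$span_hours) / nrow(s) else NA_real_

  h_w0 <- played_hours_in(win_start(7), as_of)
  h_w1 <- played_hours_in(win_start(14), win_start(7))
  h_month_weekly <- played_hours_in(win_start(35), win_start(7)) / 4

  s_w0 <- sessions_in(win_start(7), as_of)
  s_w1 <- sessions_in(win_start(14), win_start(7))
  s_month <- sessions_in(win_start(35), win_start(7))
  hps_w0 <- hps(s_w0)
  hps_w1 <- hps(s_w1)
  hps_month <- hps(s_month)

  pct <- function(cur, prev) {
    if (is.na(cur) || is.na(prev)) NA_integer_ else percent_difference(cur, prev)
  }

  # Daily buckets: 13 windows of 24 h ending at as_of, labelled by the
  # local calendar date on which each window opens.
  daily_series <- purrr::map_dfr(12:0, function(k) {
    lo <- win_start(k + 1)
    hi <- win_start(k)
    sel <- matches$started_at >= lo & matches$started_at < hi
    tibble(
      day = as_date(with_tz(lo, tz)),
      n_matches = sum(sel),
      n_sessions = nrow(sessions_in(lo, hi))
    )
  })

  structure(
    list(
      type = "recent",
      as_of = as_of,
      tz = tz,
      config = unclass(config),
      total_hours_last_7d = h_w0,
      pct_diff_hours_vs_prev_week = pct(h_w0, h_w1),
      pct_diff_hours_vs_prev_month = pct(h_w0, h_month_weekly),
      total_sessions_last_7d = nrow(s_w0),
      hours_per_session_last_7d = hps_w0,
      pct_diff_hps_vs_prev_week = pct(hps_w0, hps_w1),
      pct_diff_hps_vs_prev_month = pct(hps_w0, hps_month),
      daily_series = daily_series
    ),
    class = "gametel_recent"
  )
}

#' @export
print.gametel_recent <- function(x, ...) {
  fmt <- function(v, d = 1) ifelse(is.na(v), "-", formatC(v, format = "f", digits = d))
  fpc <- function(v) ifelse(is.na(v), "-", sprintf("%+d%%", v))
  cat("Recent gaming behavior as of ", format(x$as_of, "%Y-%m-%d %H:%M %Z"), "\n", sep = "")
  cat("  Hours last 7 days: ", fmt(x$total_hours_last_7d),
      " (", fpc(x$pct_diff_hours_vs_prev_week), " vs prev week, ",
      fpc(x$pct_diff_hours_vs_prev_month), " vs prev month)\n", sep = "")
  cat("  Sessions last 7 days: ", x$total_sessions_last_7d,
      "  Hours/session: ", fmt(x$hours_per_session_last_7d),
      " (", fpc(x$pct_diff_hps_vs_prev_week), " vs prev week, ",
      fpc(x$pct_diff_hps_vs_prev_month), " vs prev month)\n", sep = "")
  invisible(x)
}
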