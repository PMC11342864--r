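#' Historical gaming-behavior metrics
#'
#' Computes the full historical report block for one gamer over a period:
#' general totals, per-session ratios, monthly and weekly averages, and
#' day-part / weekday breakdowns. This is the metric suite a clinician
#' reviews when first assessing a patient's gaming history.
#'
#' Definitions follow the telemetry conventions used throughout the package:
#'
#' * *Played* hours sum match durations; *connected* hours sum session spans
#'   (first start to last finish, including inter-match gaps).
#' * `avg_hours_per_session` divides **connected** hours by the number of
#'   sessions (a session's duration includes its idle gaps).
#' * Monthly averages divide totals by the number of **active** calendar
#'   months (months with at least one match); weekly averages divide by
#'   active ISO weeks. Months or weeks with no play do not dilute the
#'   averages.
#' * Day-part `avg_daily_hours` divides the played hours of matches
#'   *starting* in each part by the number of calendar days in the period.
#' * A match's day part and weekday class come from its `started_at` read in
#'   the local timezone; a session is dated by its `session_start`.
#'
#' @param matches A sessionized matches tibble (see [sessionize()]) for a
#'   single gamer.
#' @param from,to Period bounds as `Date` (inclusive); matches are filtered
#'   by their local start date.
#' @param tz Olson timezone for clock-time classification.
#' @param config A [gametel_config()]; embedded in the report.
#' @return An object of class `gametel_historical`: a list of report blocks
#'   (`general`, `session_stats`, `monthly`, `weekly`, `day_part`,
#'   `weekday`) plus a per-month table `by_month` used by the chart
#'   builders. Undefined ratios (zero sessions) are `NA`.
#' @seealso [recent_stats()], [tidy.gametel_historical()],
#'   [build_chart_data()]
#' @export
historical_stats <- function(matches, from, to, tz = "UTC",
                             config = gametel_config(tz = tz)) {
  check_matches(matches)
  if (!"session_id" %in% names(matches)) {
    abort("`matches` has no `session_id`; call sessionize() first.")
  }
  from <- as_date(from)
  to <- as_date(to)
  if (is.na(from) || is.na(to) || to < from) abort("Invalid period: `to` must be >= `from`.")
  n_days <- as.numeric(to - from) + 1

  m <- matches %>%
    mutate(
      local_start = with_tz(.data$started_at, tz),
      local_date = as_date(.data$local_start),
      duration_min = secs_between(.data$started_at, .data$finished_at) / 60
    ) %>%
    filter(.data$local_date >= from, .data$local_date <= to) %>%
    mutate(
      part = classify_day_part(.data$started_at, tz),
      wclass = classify_weekday(.data$started_at, tz),
      month = format(.data$local_date, "%Y-%m"),
      week = sprintf("%d-W%02d", isoyear(.data$local_date), isoweek(.data$local_date))
    )

  sess <- if (nrow(m) > 0) session_summary(m) else
    tibble(
      session_id = character(), n_matches = integer(),
      session_start = as.POSIXct(character(), tz = "UTC"),
      session_end = as.POSIXct(character(), tz = "UTC"),
      span_hours = numeric(), played_hours = numeric()
    )

  n_matches <- nrow(m)
  n_sessions <- nrow(sess)
  played_h <- sum(m$duration_min) / 60
  connected_h <- sum(sess$span_hours)
  active_months <- dplyr::n_distinct(m$month)
  active_weeks <- dplyr::n_distinct(m$week)

  ratio <- function(num, den) if (den > 0) num / den else NA_real_

  general <- list(
    n_matches = n_matches,
    avg_match_duration_min = if (n_matches > 0) mean(m$duration_min) else NA_real_,
    total_hours_played = played_h,
    total_hours_connected = connected_h,
    n_sessions = n_sessions
  )
  session_stats <- list(
    avg_sessions_per_week = ratio(n_sessions, active_weeks),
    avg_sessions_per_month = ratio(n_sessions, active_months),
    avg_matches_per_session = ratio(n_matches, n_sessions),
    avg_hours_per_session = ratio(connected_h, n_sessions)
  )

  by_class <- function(cls) {
    mm <- m[m$wclass == cls, ]
    c(matches = nrow(mm), hours = sum(mm$duration_min) / 60)
  }
  mw <- by_class("midweek")
  we <- by_class("weekend")
  monthly <- list(
    avg_matches = ratio(n_matches, active_months),
    avg_played_hours = ratio(played_h, active_months),
    avg_matches_midweek = ratio(mw[["matches"]], active_months),
    avg_matches_weekend = ratio(we[["matches"]], active_months),
    avg_hours_midweek = ratio(mw[["hours"]], active_months),
    avg_hours_weekend = ratio(we[["hours"]], active_months),
    n_active_months = active_months
  )
  weekly <- list(
    avg_matches_per_week = ratio(n_matches, active_weeks),
    avg_played_hours_per_week = ratio(played_h, active_weeks),
    n_weeks_played = active_weeks
  )

  parts <- levels(m$part) %||% c("morning", "afternoon", "evening")
  part_hours <- vapply(parts, function(p) sum(m$duration_min[m$part == p]) / 60, numeric(1))
  day_part <- list(
    avg_daily_hours = as.list(part_hours / n_days),
    matches_fraction = as.list(vapply(
      parts, function(p) ratio(sum(m$part == p), n_matches), numeric(1)
    ))
  )
  weekday <- list(matches_fraction = list(
    midweek = ratio(mw[["matches"]], n_matches),
    weekend = ratio(we[["matches"]], n_matches)
  ))

  by_month <- monthly_table(m, sess, from, to, tz)

  structure(
    list(
      type = "historical",
      period = list(from = from, to = to),
      tz = tz,
      config = unclass(config),
      general = general,
      session_stats = session_stats,
      monthly = monthly,
      weekly = weekly,
      day_part = day_part,
      weekday = weekday,
      by_month = by_month
    ),
    class = "gametel_historical"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Per-calendar-month table over the whole period (zero-filled months kept so
# seasonal pauses show as empty bars in the charts).
monthly_table <- function(m, sess, from, to, tz) {
  months <- unique(format(seq(from, to, by = "day"), "%Y-%m"))
  base <- tibble(month = months)
  if (nrow(m) == 0) {
    return(base %>% mutate(
      n_matches = 0L, n_sessions = 0L, played_hours = 0,
      hours_morning = 0, hours_afternoon = 0, hours_evening = 0,
      hours_midweek = 0, hours_weekend = 0,
      matches_midweek = 0L, matches_weekend = 0L
    ))
  }
  per_match <- m %>%
    group_by(.data$month) %>%
    summarise(
      n_matches = n(),
      played_hours = sum(.data$duration_min) / 60,
      hours_morning = sum(.data$duration_min[.data$part == "morning"]) / 60,
      hours_afternoon = sum(.data$duration_min[.data$part == "afternoon"]) / 60,
      hours_evening = sum(.data$duration_min[.data$part == "evening"]) / 60,
      hours_midweek = sum(.data$duration_min[.data$wclass == "midweek"]) / 60,
      hours_weekend = sum(.data$duration_min[.data$wclass == "weekend"]) / 60,
      matches_midweek = sum(.data$wclass == "midweek"),
      matches_weekend = sum(.data$wclass == "weekend"),
      .groups = "drop"
    )
  per_sess <- sess %>%
    mutate(month = format(as_date(with_tz(.data$session_start, tz)), "%Y-%m")) %>%
    count(.data$month, name = "n_sessions")
  base %>%
    left_join(per_match, by = "month") %>%
    left_join(per_sess, by = "month") %>%
    mutate(
      across(c("n_matches", "n_sessions", "matches_midweek", "matches_weekend"),
             ~ as.integer(tidyr::replace_na(.x, 0L))),
      across(dplyr::starts_with("hours_") | all_of("played_hours"),
             ~ tidyr::replace_na(.x, 0))
    ) %>%
    select(
      "month", "n_matches", "n_sessions", "played_hours",
      "hours_morning", "hours_afternoon", "hours_evening",
      "hours_midweek", "hours_weekend", "matches_midweek", "matches_weekend"
    )
}

#' @export
print.gametel_historical <- function(x, ...) {
  g <- x$general
  fmt <- function(v, d = 2) ifelse(is.na(v), "-", formatC(v, format = "f", digits = d))
  cat("Historical gaming behavior ", as.character(x$period$from), " .. ",
      as.character(x$period$to), " (tz ", x$tz, ")\n", sep = "")
  cat("  Matches: ", g$n_matches, "  Sessions: ", g$n_sessions,
      "  Played: ", fmt(g$total_hours_played, 1), " h",
      "  Connected: ", fmt(g$total_hours_connected, 1), " h\n", sep = "")
  s <- x$session_stats
  cat("  Avg matches/session: ", fmt(s$avg_matches_per_session),
      "  Avg hours/session: ", fmt(s$avg_hours_per_session), "\n", sep = "")
  mo <- x$monthly
  cat("  Monthly avg: ", fmt(mo$avg_matches), " matches, ",
      fmt(mo$avg_played_hours), " h over ", mo$n_active_months,
      " active month(s)\n", sep = "")
  dp <- x$day_part$matches_fraction
  cat("  Match share morning/afternoon/evening: ",
      fmt(dp$morning), "/", fmt(dp$afternoon), "/", fmt(dp$evening), "\n", sep = "")
  invisible(x)
}
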