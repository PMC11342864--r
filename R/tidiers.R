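#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a historical report into one row per metric
#'
#' @param x A `gametel_historical` object.
#' @param ... Unused.
#' @return A tibble with columns `block`, `metric`, `value`.
#' @method tidy gametel_historical
#' @export
tidy.gametel_historical <- function(x, ...) {
  flat <- function(block, values) {
    tibble(
      block = block,
      metric = names(values),
      value = as.numeric(unlist(lapply(values, function(v) v %||% NA_real_)))
    )
  }
  bind_rows(
    flat("general", x$general),
    flat("session_stats", x$session_stats),
    flat("monthly", x$monthly),
    flat("weekly", x$weekly),
    flat("day_part", c(
      setNames(x$day_part$avg_daily_hours, paste0("avg_daily_hours_", names(x$day_part$avg_daily_hours))),
      setNames(x$day_part$matches_fraction, paste0("matches_fraction_", names(x$day_part$matches_fraction)))
    )),
    flat("weekday", setNames(
      x$weekday$matches_fraction,
      paste0("matches_fraction_", names(x$weekday$matches_fraction))
    ))
  )
}

#' One-row summary of a historical report
#'
#' @param x A `gametel_historical` object.
#' @param ... Unused.
#' @return A one-row tibble of the headline metrics.
#' @method glance gametel_historical
#' @export
glance.gametel_historical <- function(x, ...) {
  tibble(
    from = x$period$from,
    to = x$period$to,
    n_matches = x$general$n_matches,
    n_sessions = x$general$n_sessions,
    total_hours_played = x$general$total_hours_played,
    total_hours_connected = x$general$total_hours_connected,
    avg_matches_per_session = x$session_stats$avg_matches_per_session,
    avg_hours_per_session = x$session_stats$avg_hours_per_session
  )
}

#' Tidy a recent report into one row per metric
#'
#' @param x A `gametel_recent` object.
#' @param ... Unused.
#' @return A tibble with columns `metric`, `value` (the daily series is
#'   available as `x$daily_series` directly).
#' @method tidy gametel_recent
#' @export
tidy.gametel_recent <- function(x, ...) {
  fields <- c(
    "total_hours_last_7d", "pct_diff_hours_vs_prev_week",
    "pct_diff_hours_vs_prev_month", "total_sessions_last_7d",
    "hours_per_session_last_7d", "pct_diff_hps_vs_prev_week",
    "pct_diff_hps_vs_prev_month"
  )
  tibble(
    metric = fields,
    value = as.numeric(unlist(lapply(x[fields], function(v) v %||% NA_real_)))
  )
}

#' One-row summary of a recent report
#'
#' @param x A `gametel_recent` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance gametel_recent
#' @export
glance.gametel_recent <- function(x, ...) {
  tibble(
    as_of = x$as_of,
    total_hours_last_7d = x$total_hours_last_7d,
    total_sessions_last_7d = x$total_sessions_last_7d,
    hours_per_session_last_7d = x$hours_per_session_last_7d
  )
}
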