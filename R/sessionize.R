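#' Inter-match gaps
#'
#' The idle time between consecutive matches: the gap between one match's
#' `finished_at` and the next match's `started_at`, in minutes. Overlapping
#' matches (next starting before the previous ended, as telemetry sometimes
#' reports) yield a gap of 0 rather than a negative value.
#'
#' @param matches A matches tibble sorted by `started_at` (single gamer).
#' @return Numeric vector of gaps in minutes, length `nrow(matches) - 1`
#'   (empty for fewer than two matches).
#' @export
#' @examples
#' m <- tibble::tibble(
#'   match_id = c("a", "b"), gamer_id = "g",
#'   started_at = as.POSIXct(c("2021-01-01 10:00", "2021-01-01 11:00"), tz = "UTC"),
#'   finished_at = as.POSIXct(c("2021-01-01 10:40", "2021-01-01 11:35"), tz = "UTC")
#' )
#' inter_match_gaps(m) # 20 minutes
inter_match_gaps <- function(matches) {
  check_matches(matches, need_sorted = TRUE)
  if (nrow(matches) < 2) return(numeric(0))
  gaps <- secs_between(
    matches$finished_at[-nrow(matches)],
    matches$started_at[-1]
  ) / 60
  pmax(gaps, 0)
}

#' Derive a session gap threshold from observed gaps
#'
#' The session boundary threshold is an empirical quantile of the
#' inter-match-gap distribution; the default 60th percentile reproduces how
#' the 30-minute rule is calibrated from real histories. Uses linear
#' interpolation between order statistics.
#'
#' @param gaps Numeric vector of gaps in minutes (from [inter_match_gaps()]).
#' @param quantile Probability in (0, 1); default 0.60.
#' @param type Quantile definition (see [stats::quantile()]); default 7,
#'   linear interpolation.
#' @return Threshold in minutes (scalar).
#' @export
#' @examples
#' derive_gap_threshold(1:100) # 60.4
derive_gap_threshold <- function(gaps, quantile = 0.60, type = 7) {
  if (length(gaps) == 0) {
    abort("No gaps to derive a threshold from; use the default 30-minute threshold.")
  }
  stopifnot(quantile > 0, quantile < 1)
  unname(stats::quantile(gaps, probs = quantile, type = type, names = FALSE))
}

#' Partition a match history into gaming sessions
#'
#' A session is a maximal run of consecutive matches separated by less than
#' the gap threshold; a gap at or above the threshold starts a new session
#' (so a threshold of 0 yields all singletons). Matches must already be
#' sorted by `started_at` — unsorted input is an error, not silently sorted.
#'
#' @param matches A matches tibble sorted by `started_at` (single gamer).
#' @param gap_threshold_min Threshold in minutes (default 30).
#' @return The input tibble with a `session_id` column (`"s0001"`, ... in
#'   chronological order) added.
#' @seealso [session_summary()] for one-row-per-session aggregates.
#' @export
sessionize <- function(matches, gap_threshold_min = 30) {
  check_matches(matches)
  stopifnot(gap_threshold_min >= 0)
  if (nrow(matches) > 1 && is.unsorted(matches$started_at)) {
    abort("`matches` must be sorted by `started_at` before sessionizing.")
  }
  if (nrow(matches) == 0) {
    return(mutate(matches, session_id = character(0)))
  }
  gaps <- inter_match_gaps(matches)
  new_session <- c(TRUE, gaps >= gap_threshold_min)
  idx <- cumsum(new_session)
  mutate(matches, session_id = sprintf("s%04d", idx))
}

#' Summarize sessions
#'
#' One row per session: bounds, span (first start to last finish, the
#' "connected" time including inter-match gaps) and played duration (sum of
#' match durations).
#'
#' @param matches A sessionized matches tibble (see [sessionize()]).
#' @return A tibble with one row per `session_id`: `n_matches`,
#'   `session_start`, `session_end`, `span_hours`, `played_hours`.
#' @export
session_summary <- function(matches) {
  check_matches(matches)
  if (!"session_id" %in% names(matches)) {
    abort("`matches` has no `session_id`; call sessionize() first.")
  }
  matches %>%
    group_by(.data$session_id) %>%
    summarise(
      n_matches = n(),
      session_start = min(.data$started_at),
      session_end = max(.data$finished_at),
      span_hours = secs_between(min(.data$started_at), max(.data$finished_at)) / 3600,
      played_hours = sum(secs_between(.data$started_at, .data$finished_at)) / 3600,
      .groups = "drop"
    ) %>%
    arrange(.data$session_start)
}

#' Classify clock time into day parts
#'
#' Maps a timestamp to `morning`, `afternoon` or `evening` by its local
#' clock hour, using three half-open 8-hour blocks: morning \[06:00, 14:00),
#' afternoon \[14:00, 22:00), evening \[22:00, 06:00). Every clock time
#' belongs to exactly one part.
#'
#' @param timestamp POSIXct vector.
#' @param tz Olson timezone used to read the clock (default `"UTC"`).
#' @return Factor with levels `morning`, `afternoon`, `evening`.
#' @export
#' @examples
#' t <- as.POSIXct("2021-06-01 23:30", tz = "UTC")
#' classify_day_part(t) # evening
classify_day_part <- function(timestamp, tz = "UTC") {
  h <- hour(with_tz(timestamp, tz))
  part <- case_when(
    h >= 6 & h < 14 ~ "morning",
    h >= 14 & h < 22 ~ "afternoon",
    TRUE ~ "evening"
  )
  factor(part, levels = c("morning", "afternoon", "evening"))
}

#' Classify timestamps as midweek or weekend
#'
#' Monday through Friday are `midweek`; Saturday and Sunday are `weekend`.
#' A match is classified by its local start date.
#'
#' @inheritParams classify_day_part
#' @return Factor with levels `midweek`, `weekend`.
#' @export
classify_weekday <- function(timestamp, tz = "UTC") {
  wd <- wday(with_tz(timestamp, tz), week_start = 1) # 1 = Monday
  factor(
    if_else(wd >= 6, "weekend", "midweek"),
    levels = c("midweek", "weekend")
  )
}
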