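# Round half away from zero (report-style rounding; base round() is banker's).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Signed percent difference between two nonnegative quantities
#'
#' Week-over-week style change indicator: `100 * (current - previous) /
#' previous`, rounded half away from zero to a signed integer percent. When
#' the baseline is zero the change is undefined and `NA` is returned.
#'
#' @param current,previous Nonnegative numeric scalars (or equal-length
#'   vectors, compared elementwise).
#' @return Integer percent(s); `NA_integer_` where `previous` is 0 or either
#'   input is `NA`.
#' @export
#' @examples
#' percent_difference(15, 10) # 50
#' percent_difference(8.5, 17) # -50
#' percent_difference(3, 0) # NA: no baseline
percent_difference <- function(current, previous) {
  if (length(current) != length(previous)) {
    abort("`current` and `previous` must have the same length.")
  }
  bad <- !is.na(current) & !is.na(previous) & (current < 0 | previous < 0)
  if (any(bad)) abort("percent_difference() requires nonnegative inputs.")
  out <- rep(NA_integer_, length(current))
  ok <- !is.na(current) & !is.na(previous) & previous > 0
  out[ok] <- as.integer(round_half_away(100 * (current[ok] - previous[ok]) / previous[ok]))
  out
}

#' Default analysis configuration
#'
#' Bundles the tunable analysis parameters that reports embed for
#' reproducibility: the local timezone used for clock-time classification,
#' the session gap threshold in minutes, the quantile type used when deriving
#' a threshold from data, and report rounding digits.
#'
#' @param tz Olson timezone name used to classify day parts and weekdays
#'   (timestamps are stored in UTC; classification happens in local time).
#' @param gap_threshold_min Inter-match gap (minutes) at or above which a new
#'   session starts.
#' @param quantile_type Quantile definition passed to [stats::quantile()]
#'   when deriving the threshold from observed gaps (7 = linear
#'   interpolation between order statistics).
#' @param hours_digits,percent_digits Rounding used when formatting reports.
#' @return A named list with class `gametel_config`.
#' @export
#' @examples
#' gametel_config(tz = "Europe/Lisbon")
gametel_config <- function(tz = "UTC", gap_threshold_min = 30,
                           quantile_type = 7, hours_digits = 2,
                           percent_digits = 0) {
  stopifnot(gap_threshold_min > 0)
  structure(
    list(
      tz = tz, gap_threshold_min = gap_threshold_min,
      quantile_type = quantile_type, hours_digits = hours_digits,
      percent_digits = percent_digits
    ),
    class = "gametel_config"
  )
}

# Integer seconds between two POSIXct vectors.
secs_between <- function(from, to) as.numeric(difftime(to, from, units = "secs"))

# Validate a matches tibble has the expected columns.
check_matches <- function(matches, need_sorted = FALSE) {
  required <- c("match_id", "gamer_id", "started_at", "finished_at")
  missing <- setdiff(required, names(matches))
  if (length(missing) > 0) {
    abort(paste0("`matches` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (need_sorted && nrow(matches) > 1 && is.unsorted(matches$started_at)) {
    abort("`matches` must be sorted by `started_at`; call read_matches() or arrange() first.")
  }
  invisible(matches)
}

check_frames <- function(frames) {
  required <- c("stream_id", "t", EMOTIONS)
  missing <- setdiff(required, names(frames))
  if (length(missing) > 0) {
    abort(paste0("emotion frames are missing column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(frames)
}
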