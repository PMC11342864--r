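# Builders and independent oracles shared across the test files.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# Matches tibble from start times (strings or POSIXct) and durations (minutes).
make_matches <- function(starts, durations_min, gamer_id = "g1",
                         ids = sprintf("m%03d", seq_along(starts))) {
  if (!inherits(starts, "POSIXct")) starts <- utc(starts)
  tibble::tibble(
    match_id = ids,
    gamer_id = gamer_id,
    started_at = starts,
    finished_at = starts + durations_min * 60,
    kills = 10L, deaths = 10L, assists = 2L,
    duration_min = as.numeric(durations_min)
  )
}

# Random single-gamer history: n matches with random gaps, sorted.
random_history <- function(n, origin = "2023-01-01 10:00:00") {
  dur <- runif(n, 20, 60)
  gaps <- runif(n, 0, 90) # minutes between finish and next start
  starts <- utc(origin) + cumsum(c(0, (dur[-n] + gaps[-n]) * 60))
  make_matches(format(starts, "%Y-%m-%d %H:%M:%S"), dur)
}

# Independent pairwise-scan sessionization oracle: returns integer session
# index per match by scanning every consecutive pair.
oracle_sessionize <- function(matches, threshold_min) {
  n <- nrow(matches)
  if (n == 0) return(integer(0))
  idx <- integer(n)
  idx[1] <- 1L
  for (i in 2:n) {
    gap <- max(0, as.numeric(difftime(
      matches$started_at[i], matches$finished_at[i - 1],
      units = "mins"
    )))
    idx[i] <- if (gap >= threshold_min) idx[i - 1] + 1L else idx[i - 1]
  }
  idx
}

session_index <- function(session_id) {
  as.integer(factor(session_id, levels = unique(session_id)))
}

# Sort-based linearly interpolated quantile oracle (independent of
# stats::quantile): position p*(n-1)+1 between order statistics.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- p * (length(s) - 1) + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Brute-force trailing-window median smoothing oracle.
oracle_smooth <- function(frames, window_s = 5) {
  frames <- frames[order(frames$t), ]
  out <- frames
  for (ch in emotion_channels()) {
    out[[ch]] <- vapply(seq_len(nrow(frames)), function(i) {
      sel <- frames$t >= frames$t[i] - window_s + 1 & frames$t <= frames$t[i]
      stats::median(frames[[ch]][sel])
    }, numeric(1))
  }
  out
}

# Brute-force window-median oracle for one event.
oracle_event_median <- function(frames, t_event, half = 3) {
  sel <- frames$t >= t_event - half & frames$t <= t_event + half
  vapply(emotion_channels(), function(ch) stats::median(frames[[ch]][sel]), numeric(1))
}

# Random normalized emotion frames (possibly with missing seconds).
random_frames <- function(n, stream_id = "v1", drop = 0) {
  t <- 0:(n - 1)
  if (drop > 0) t <- sort(sample(t, n - drop))
  vals <- matrix(runif(length(t) * 7, 0, 10), ncol = 7)
  vals <- vals / rowSums(vals) * 100
  colnames(vals) <- emotion_channels()
  tibble::tibble(stream_id = stream_id, t = t, !!!as.data.frame(vals))
}

# Engineered single-gamer history realizing exact summary counts:
# `n_sessions` sessions, `n_matches` matches, total session span equal to
# `connected_hours` (sessions separated by 2 h so a 30-min threshold
# recovers them).
engineered_history <- function(n_matches, n_sessions, connected_hours,
                               origin = "2021-01-04 10:00:00") {
  per <- rep(n_matches %/% n_sessions, n_sessions)
  extra <- n_matches %% n_sessions
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  span_min <- connected_hours * 60 / n_sessions
  start <- utc(origin)
  rows <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    k <- per[s]
    gap <- if (k > 1) min(10, span_min / (2 * (k - 1))) else 0
    dur <- (span_min - (k - 1) * gap) / k
    stopifnot(dur > 0)
    starts <- start + cumsum(c(0, rep(dur + gap, k - 1))) * 60
    rows[[s]] <- tibble::tibble(
      started_at = starts,
      finished_at = starts + dur * 60
    )
    start <- starts[k] + dur * 60 + 120 * 60 # 2 h to the next session
  }
  out <- dplyr::bind_rows(rows)
  make_matches(
    out$started_at,
    as.numeric(difftime(out$finished_at, out$started_at, units = "mins")),
    ids = sprintf("m%05d", seq_len(nrow(out)))
  )
}
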