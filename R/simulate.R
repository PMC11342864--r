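#' Gamer behavior profile for the synthetic-data generator
#'
#' Bundles the behavioral parameters of a simulated gamer. The two built-in
#' archetypes mirror the qualitative patterns of amateur and professional
#' competitive players: amateurs play short evening-dominant sessions after
#' work or school and pause for a vacation month; professionals play long,
#' frequent, more day-balanced sessions.
#'
#' Distributions: matches per session are shifted-geometric with the stated
#' mean (support >= 1); match durations are normal(40, 5) minutes clipped to
#' \[20, 70\]; intra-session gaps are lognormal with the stated median
#' (clipped below the session threshold so generated sessions are true
#' sessions).
#'
#' @param kind `"amateur"` or `"professional"`; sets archetype defaults.
#' @param sessions_per_week_rate Expected sessions per week (Poisson).
#' @param matches_per_session_mean Mean matches per session (>= 1).
#' @param match_duration_mean_min,match_duration_sd_min,match_duration_range_min
#'   Match-duration model (normal, clipped to the range).
#' @param intra_gap_median_min,intra_gap_sdlog Lognormal intra-session gap
#'   model; the median must stay below the 30-minute session threshold.
#' @param day_part_mix Named probability vector over
#'   `morning`/`afternoon`/`evening` for session start parts.
#' @param weekend_fraction Expected fraction of sessions on weekend days.
#' @param off_months Integer months (1-12) with zero play (seasonal pause).
#' @param seed Default seed used by [generate_history()].
#' @return A list with class `gamer_profile`.
#' @export
#' @examples
#' gamer_profile("professional", seed = 7)
gamer_profile <- function(kind = c("amateur", "professional"),
                          sessions_per_week_rate = NULL,
                          matches_per_session_mean = NULL,
                          match_duration_mean_min = 40,
                          match_duration_sd_min = 5,
                          match_duration_range_min = c(20, 70),
                          intra_gap_median_min = 10,
                          intra_gap_sdlog = 0.5,
                          day_part_mix = NULL,
                          weekend_fraction = NULL,
                          off_months = NULL,
                          seed = 1L) {
  kind <- match.arg(kind)
  defaults <- if (kind == "amateur") {
    list(
      sessions_per_week_rate = 5,
      matches_per_session_mean = 1.8,
      day_part_mix = c(morning = 0.01, afternoon = 0.09, evening = 0.90),
      weekend_fraction = 0.27,
      off_months = 8L # vacation month with zero play
    )
  } else {
    list(
      sessions_per_week_rate = 3.5,
      matches_per_session_mean = 5.3,
      day_part_mix = c(morning = 0.06, afternoon = 0.40, evening = 0.54),
      weekend_fraction = 0.22,
      off_months = integer(0)
    )
  }
  p <- list(
    profile_kind = kind,
    sessions_per_week_rate = sessions_per_week_rate %||% defaults$sessions_per_week_rate,
    matches_per_session_mean = matches_per_session_mean %||% defaults$matches_per_session_mean,
    match_duration_mean_min = match_duration_mean_min,
    match_duration_sd_min = match_duration_sd_min,
    match_duration_range_min = match_duration_range_min,
    intra_gap_median_min = intra_gap_median_min,
    intra_gap_sdlog = intra_gap_sdlog,
    day_part_mix = day_part_mix %||% defaults$day_part_mix,
    weekend_fraction = weekend_fraction %||% defaults$weekend_fraction,
    off_months = as.integer(off_months %||% defaults$off_months),
    seed = as.integer(seed)
  )
  stopifnot(
    p$sessions_per_week_rate >= 0,
    p$matches_per_session_mean >= 1,
    abs(sum(p$day_part_mix) - 1) < 1e-9,
    p$weekend_fraction >= 0, p$weekend_fraction <= 1,
    p$intra_gap_median_min > 0, p$intra_gap_median_min < 30
  )
  structure(p, class = "gamer_profile")
}

#' Derive per-component seeds from one root seed
#'
#' Streams a single root seed into independent sub-seeds so the match
#' history, event logs and emotion streams of one simulated study can be
#' regenerated independently. Leaves the caller's RNG state untouched.
#'
#' @param seed Root integer seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of `n` seeds (all below 2^31).
#' @export
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic match history with known session structure
#'
#' Draws sessions day by day (Poisson counts, with weekend/midweek rates set
#' by `weekend_fraction`), places each session inside its day part's clock
#' block, and fills it with matches separated by sub-threshold gaps.
#' Consecutive sessions are kept at least `gap_threshold_min` apart, so the
#' generated partition is exactly recoverable by [sessionize()]; the true
#' partition is returned alongside the matches for recovery tests.
#'
#' Sessions are placed so they fit inside both their clock block and their
#' calendar day whenever possible; a session too long for its block is
#' anchored at the block start and allowed to run over (as real sessions
#' do), and a session whose block is fully occupied by earlier sessions is
#' packed immediately after its predecessor. These two fallbacks are the
#' only sources of drift between the planted day-part / weekday mix and the
#' realized match fractions; session and match counts are never affected.
#'
#' @param profile A [gamer_profile()].
#' @param from,to Period bounds (`Date`, inclusive).
#' @param seed Integer seed (defaults to `profile$seed`); identical seeds
#'   give identical histories.
#' @param gamer_id Identifier stamped on the generated matches.
#' @param gap_threshold_min Session threshold the history is generated
#'   against (default 30).
#' @return A list: `matches` (tibble sorted by `started_at`, UTC), `truth`
#'   (tibble `match_id`, `session_id` — the generator's partition), and
#'   `profile`.
#' @export
generate_history <- function(profile, from, to, seed = profile$seed,
                             gamer_id = "g1", gap_threshold_min = 30) {
  stopifnot(inherits(profile, "gamer_profile"))
  from <- as_date(from)
  to <- as_date(to)
  if (is.na(from) || is.na(to) || to < from) abort("Invalid period: `to` must be >= `from`.")
  set.seed(seed)

  days <- seq(from, to, by = "day")
  mon <- as.integer(format(days, "%m"))
  eligible <- !(mon %in% profile$off_months)
  is_weekend <- wday(days, week_start = 1) >= 6
  rate <- ifelse(
    is_weekend,
    profile$sessions_per_week_rate * profile$weekend_fraction / 2,
    profile$sessions_per_week_rate * (1 - profile$weekend_fraction) / 5
  )
  rate[!eligible] <- 0
  n_per_day <- rpois(length(days), rate)

  parts <- c("morning", "afternoon", "evening")
  sessions <- list()
  si <- 0L
  for (d in seq_along(days)) {
    nd <- n_per_day[d]
    if (nd == 0) next
    for (k in seq_len(nd)) {
      si <- si + 1L
      part <- sample(parts, 1, prob = profile$day_part_mix)
      n_m <- 1L + rgeom(1, prob = 1 / profile$matches_per_session_mean)
      dur <- pmin(
        pmax(
          rnorm(n_m, profile$match_duration_mean_min, profile$match_duration_sd_min),
          profile$match_duration_range_min[1]
        ),
        profile$match_duration_range_min[2]
      )
      gaps <- if (n_m > 1) {
        pmin(
          rlnorm(n_m - 1, log(profile$intra_gap_median_min), profile$intra_gap_sdlog),
          gap_threshold_min - 1
        )
      } else {
        numeric(0)
      }
      span_h <- (sum(dur) + sum(gaps)) / 60
      sessions[[si]] <- list(
        day = days[d], part = part, dur = dur, gaps = gaps, span_h = span_h
      )
    }
  }
  if (length(sessions) == 0) {
    empty <- tibble(
      match_id = character(), gamer_id = character(),
      started_at = as.POSIXct(character(), tz = "UTC"),
      finished_at = as.POSIXct(character(), tz = "UTC"),
      kills = integer(), deaths = integer(), assists = integer(),
      duration_min = numeric()
    )
    return(list(
      matches = empty,
      truth = tibble(match_id = character(), session_id = character()),
      profile = profile
    ))
  }

  # Place sessions chronologically, sampling each start uniformly from the
  # part of its clock block still feasible after the previous session (>=
  # threshold + 1 min of head-room, so the planted partition is the unique
  # one). A session whose block is exhausted on its day slides to the same
  # part on a following day; an oversize session anchors at its block start
  # and runs over. Sessions are never dropped, so the planted rates are
  # preserved exactly.
  min_sep <- (gap_threshold_min + 1) * 60
  start_at <- numeric(length(sessions))
  prev_end <- -Inf
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    day0 <- as.numeric(as.POSIXct(s$day, tz = "UTC"))
    st <- NA_real_
    for (offset in 0:7) {
      day_o <- s$day + offset
      if (day_o > to || as.integer(format(day_o, "%m")) %in% profile$off_months) break
      base <- day0 + offset * 86400
      lo_h <- (prev_end + min_sep - base) / 3600
      h <- draw_start_hour(s$part, s$span_h, lo_h)
      if (!is.na(h)) {
        st <- base + h * 3600
        break
      }
    }
    if (is.na(st)) {
      # oversize for its block: anchor at the block start (evening opens at
      # 22:00 and legitimately runs across midnight) and run over; when the
      # following day is outside the period or an off month, the evening
      # anchor moves to the block's early-morning side so no match spills
      # into an ineligible day
      next_day <- s$day + 1
      next_ok <- next_day <= to &&
        !(as.integer(format(next_day, "%m")) %in% profile$off_months)
      anchor_h <- switch(s$part,
        morning = 6, afternoon = 14,
        evening = if (next_ok) 22 else 0
      )
      st <- max(day0 + anchor_h * 3600, prev_end + min_sep)
    }
    start_at[i] <- st
    prev_end <- st + s$span_h * 3600
  }

  rows <- purrr::map_dfr(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    starts <- start_at[i] + cumsum(c(0, s$dur[-length(s$dur)] + s$gaps)) * 60
    tibble(
      session_id = sprintf("s%04d", i),
      started_at = as.POSIXct(starts, tz = "UTC", origin = "1970-01-01"),
      finished_at = as.POSIXct(starts + s$dur * 60, tz = "UTC", origin = "1970-01-01")
    )
  })
  n <- nrow(rows)
  matches <- rows %>%
    mutate(
      match_id = sprintf("m%05d", row_number()),
      gamer_id = gamer_id,
      kills = rpois(n, 18),
      deaths = rpois(n, 16),
      assists = rpois(n, 4),
      duration_min = secs_between(.data$started_at, .data$finished_at) / 60
    )
  list(
    matches = matches %>%
      select(
        "match_id", "gamer_id", "started_at", "finished_at",
        "kills", "deaths", "assists", "duration_min"
      ),
    truth = matches %>% select("match_id", "session_id"),
    profile = profile
  )
}

# Start hour (fractional, 0-24) for a session of span_h hours in a day
# part, constrained to start no earlier than lo_h. Samples uniformly over
# the start positions for which the whole session fits inside both the
# part's clock block and the calendar day; NA when no such position exists.
draw_start_hour <- function(part, span_h, lo_h = -Inf) {
  windows <- switch(part,
    morning = list(c(6, 14 - span_h)),
    afternoon = list(c(14, 22 - span_h)),
    evening = list(c(0, 6 - span_h), c(22, 24 - span_h))
  )
  windows <- purrr::map(windows, function(w) c(max(w[1], lo_h), w[2]))
  windows <- purrr::keep(windows, ~ .x[2] >= .x[1])
  if (length(windows) == 0) return(NA_real_)
  len <- vapply(windows, function(w) w[2] - w[1], numeric(1))
  w <- windows[[sample.int(length(windows), 1, prob = len + 1e-9)]]
  runif(1, w[1], w[2])
}

#' Emotion profile for the synthetic stream generator
#'
#' Defines a gamer's baseline emotional mix, the per-second noise level, and
#' additive event-triggered responses (e.g. an anger surge after a death).
#'
#' @param baseline_mix Named 7-vector of mean percentages (must sum to 100).
#' @param concentration Dirichlet concentration controlling per-second
#'   noise; larger is calmer. `Inf` gives a constant baseline stream.
#' @param event_effects Tibble with columns `kind`, `emotion`, `magnitude`
#'   (percentage points added) and `duration_s`; an effect raises its
#'   channel for the onset second plus `duration_s` following seconds, with
#'   the other channels rescaled so every frame still sums to 100.
#' @param seed Default seed used by [generate_emotion_stream()].
#' @return A list with class `emotion_profile`.
#' @export
emotion_profile <- function(baseline_mix = c(
                              angry = 15, disgust = 2, fear = 10, happy = 8,
                              sad = 12, surprise = 3, neutral = 50
                            ),
                            concentration = 150,
                            event_effects = default_event_effects(),
                            seed = 1L) {
  stopifnot(
    setequal(names(baseline_mix), EMOTIONS),
    abs(sum(baseline_mix) - 100) < 1e-6,
    all(baseline_mix >= 0),
    concentration > 0
  )
  structure(
    list(
      baseline_mix = baseline_mix[EMOTIONS],
      concentration = concentration,
      event_effects = event_effects,
      seed = as.integer(seed)
    ),
    class = "emotion_profile"
  )
}

default_event_effects <- function() {
  tibble(
    kind = c("kill", "death", "round_end"),
    emotion = c("angry", "sad", "fear"),
    magnitude = c(15, 20, 15),
    duration_s = c(2L, 3L, 3L)
  )
}

#' Generate a synthetic per-second emotion stream
#'
#' Per-second frames are Dirichlet draws around the profile baseline,
#' scaled to percentages; event effects then raise their target channel by
#' the planted number of percentage points for the onset second plus
#' `duration_s` following seconds, with the remaining channels rescaled so
#' each frame still sums to 100. The planted magnitudes are therefore
#' recoverable by the event-aligned median analytics.
#'
#' @param profile An [emotion_profile()].
#' @param duration_s Stream length in seconds (frames at `t = 0 ..
#'   duration_s - 1`).
#' @param events Optional events tibble (`t`, `kind`); only kinds with a
#'   configured effect alter the stream.
#' @param stream_id Identifier stamped on the frames.
#' @param seed Integer seed (defaults to `profile$seed`).
#' @return An emotion-frame tibble (`stream_id`, `t`, seven channels), each
#'   row summing to 100.
#' @export
generate_emotion_stream <- function(profile, duration_s, events = NULL,
                                    stream_id = "v0001", seed = profile$seed) {
  stopifnot(inherits(profile, "emotion_profile"), duration_s >= 1)
  set.seed(seed)
  base <- profile$baseline_mix
  n <- as.integer(duration_s)
  if (is.finite(profile$concentration)) {
    shape <- profile$concentration * base / 100
    g <- matrix(
      rgamma(n * length(EMOTIONS), shape = rep(shape, each = n)),
      nrow = n
    )
    vals <- g / rowSums(g) * 100
  } else {
    vals <- matrix(rep(base, each = n), nrow = n)
  }
  colnames(vals) <- EMOTIONS

  if (!is.null(events) && nrow(events) > 0 && nrow(profile$event_effects) > 0) {
    for (i in seq_len(nrow(events))) {
      eff <- profile$event_effects[profile$event_effects$kind == events$kind[i], ]
      if (nrow(eff) == 0) next
      for (j in seq_len(nrow(eff))) {
        sec <- events$t[i]:(events$t[i] + eff$duration_s[j])
        sec <- sec[sec >= 0 & sec < n]
        if (length(sec) == 0) next
        rows <- sec + 1L
        ch <- eff$emotion[j]
        bumped <- pmin(vals[rows, ch] + eff$magnitude[j], 100)
        others <- setdiff(EMOTIONS, ch)
        other_sum <- rowSums(vals[rows, others, drop = FALSE])
        scale <- ifelse(other_sum > 0, (100 - bumped) / other_sum, 0)
        vals[rows, others] <- vals[rows, others, drop = FALSE] * scale
        vals[rows, ch] <- bumped
      }
    }
  }
  tibble(stream_id = stream_id, t = 0:(n - 1L), !!!as.data.frame(vals))
}

#' Generate a synthetic in-game event log
#'
#' Rounds alternate `round_start`/`round_end` on a fixed cadence; kills and
#' deaths are placed uniformly at random with a minimum separation from
#' every other event so event-aligned windows stay uncontaminated.
#'
#' @param duration_s Stream length in seconds.
#' @param n_kills,n_deaths Numbers of kill/death events.
#' @param round_every_s Round length in seconds (0 disables round events).
#' @param min_sep_s Minimum spacing between any two events.
#' @param stream_id Identifier stamped on the events.
#' @param seed Integer seed.
#' @return An events tibble (`stream_id`, `t`, `kind`) sorted by `t`.
#' @export
generate_events <- function(duration_s, n_kills = 5, n_deaths = 5,
                            round_every_s = 120, min_sep_s = 8,
                            stream_id = "v0001", seed = 1L) {
  set.seed(seed)
  taken <- integer(0)
  ev <- list()
  if (round_every_s > 0) {
    starts <- seq(0L, duration_s - 1L, by = as.integer(round_every_s))
    ends <- pmin(starts + as.integer(round_every_s) - 1L, duration_s - 1L)
    ev[["round_start"]] <- starts
    ev[["round_end"]] <- ends
    taken <- c(starts, ends)
  }
  place <- function(k) {
    out <- integer(0)
    tries <- 0L
    while (length(out) < k && tries < 10000L) {
      cand <- sample.int(duration_s, 1) - 1L
      if (all(abs(cand - c(taken, out)) >= min_sep_s)) out <- c(out, cand)
      tries <- tries + 1L
    }
    if (length(out) < k) {
      warn("Could not place all events with the requested separation; log is shorter.")
    }
    out
  }
  kills <- place(n_kills)
  taken <- c(taken, kills)
  deaths <- place(n_deaths)
  bind_rows(
    tibble(t = ev[["round_start"]] %||% integer(0), kind = "round_start"),
    tibble(t = ev[["round_end"]] %||% integer(0), kind = "round_end"),
    tibble(t = kills, kind = "kill"),
    tibble(t = deaths, kind = "death")
  ) %>%
    mutate(stream_id = stream_id) %>%
    select("stream_id", "t", "kind") %>%
    arrange(.data$t)
}
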