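#' Smooth an emotion stream with a trailing 5-second median
#'
#' Replaces each channel value at second `t` by the median of the raw values
#' observed in the causal window `{t-4, ..., t}` (only seconds actually
#' present in the stream contribute; the first seconds use the available
#' prefix). Smoothing each of the seven channels independently suppresses
#' one-second recognition spikes while keeping traces aligned with the
#' events that caused them. The output is deliberately **not** renormalized:
#' channel-wise medians do not preserve the sum-to-100 property, so smoothed
#' frames are meant for plotting, while summaries are computed on raw
#' frames.
#'
#' @param frames An emotion-frame tibble (sorted output of
#'   [read_emotion_stream()] or [generate_emotion_stream()]).
#' @param window_s Trailing window length in seconds (default 5).
#' @return A tibble of the same shape with smoothed channel values.
#' @export
smooth_stream <- function(frames, window_s = 5) {
  check_frames(frames)
  stopifnot(window_s >= 1)
  if (nrow(frames) == 0) return(frames)
  frames %>%
    group_by(.data$stream_id) %>%
    dplyr::group_modify(~ smooth_one(.x, window_s)) %>%
    ungroup()
}

smooth_one <- function(df, window_s) {
  df <- arrange(df, .data$t)
  t <- df$t
  # window for row i: rows with t in [t[i]-window_s+1, t[i]]
  lo <- findInterval(t - window_s + 1 - 0.5, t) + 1L
  for (ch in EMOTIONS) {
    v <- df[[ch]]
    df[[ch]] <- vapply(
      seq_along(v),
      function(i) median(v[lo[i]:i]),
      numeric(1)
    )
  }
  df
}

#' Per-event emotion medians in a symmetric window
#'
#' For each event, takes the median of each emotion channel over the frames
#' within `half_window_s` seconds of the event (inclusive on both sides, so
#' at most `2 * half_window_s + 1` frames); frames outside the stream's
#' range are simply absent, so windows at stream boundaries are truncated.
#'
#' @param frames An emotion-frame tibble.
#' @param events An events tibble (`stream_id, t, kind`); every event must
#'   have at least one frame in its window.
#' @param half_window_s Half window in seconds (default 3).
#' @return A tibble with one row per event: `stream_id`, `t`, `kind`, the 7
#'   per-channel medians, `n_frames`, and `scope = "event"`.
#' @export
event_emotion_medians <- function(frames, events, half_window_s = 3) {
  check_frames(frames)
  stopifnot(half_window_s >= 0, nrow(events) > 0)
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    w <- frames[
      frames$stream_id == ev$stream_id &
        frames$t >= ev$t - half_window_s &
        frames$t <= ev$t + half_window_s,
    ]
    if (nrow(w) == 0) {
      abort(paste0(
        "No frames within ", half_window_s, " s of ", ev$kind,
        " event at t=", ev$t, " in stream ", ev$stream_id, "."
      ))
    }
    med <- vapply(EMOTIONS, function(ch) median(w[[ch]]), numeric(1))
    tibble(
      stream_id = ev$stream_id, t = ev$t, kind = ev$kind,
      !!!as.list(med), n_frames = nrow(w), scope = "event"
    )
  })
}

#' Aggregate per-event medians by event kind
#'
#' The report-table contract: one row per event kind, each channel being the
#' median across the per-event medians of all events of that kind
#' (median-of-medians, robust to unequal window truncation at stream
#' boundaries). Kinds with no events yield an all-`NA` row.
#'
#' @inheritParams event_emotion_medians
#' @param kinds Event kinds to report (default: the four standard kinds).
#' @return A tibble with one row per kind: the 7 channels, `n_events`, and
#'   `scope = "event"`.
#' @export
aggregate_event_medians <- function(frames, events, half_window_s = 3,
                                    kinds = c("kill", "death", "round_start", "round_end")) {
  per_event <- if (nrow(events) > 0) {
    event_emotion_medians(frames, events, half_window_s)
  } else {
    NULL
  }
  purrr::map_dfr(kinds, function(k) {
    pe <- if (is.null(per_event)) NULL else per_event[per_event$kind == k, ]
    if (is.null(pe) || nrow(pe) == 0) {
      vals <- setNames(rep(NA_real_, length(EMOTIONS)), EMOTIONS)
      n <- 0L
    } else {
      vals <- vapply(EMOTIONS, function(ch) median(pe[[ch]]), numeric(1))
      n <- nrow(pe)
    }
    tibble(kind = k, !!!as.list(vals), n_events = n, scope = "event")
  })
}

#' Per-match emotion averages
#'
#' The mean of each emotion channel across a whole match recording,
#' disregarding specific events — the most stable per-match emotional
#' fingerprint. Means of normalized frames again sum to 100.
#'
#' @param frames An emotion-frame tibble (one stream per match).
#' @param t_start,t_end Optional window bounds in stream seconds
#'   (inclusive); defaults to each stream's full range.
#' @return A tibble with one row per stream: the 7 channel means,
#'   `n_frames`, and `scope = "match"`. Streams with no frames in the
#'   window are dropped.
#' @export
match_emotion_average <- function(frames, t_start = NULL, t_end = NULL) {
  check_frames(frames)
  f <- frames
  if (!is.null(t_start)) f <- f[f$t >= t_start, ]
  if (!is.null(t_end)) f <- f[f$t <= t_end, ]
  if (nrow(f) == 0) {
    return(tibble(
      stream_id = character(),
      !!!setNames(rep(list(numeric()), length(EMOTIONS)), EMOTIONS),
      n_frames = integer(), scope = character()
    ))
  }
  f %>%
    group_by(.data$stream_id) %>%
    summarise(across(all_of(EMOTIONS), mean), n_frames = n(), .groups = "drop") %>%
    mutate(scope = "match")
}

#' First / last five-minute emotion averages
#'
#' Contrasts the emotional state at the start and end of each match: the
#' per-channel mean over the first and last `span_s` seconds of each
#' stream. When a stream is shorter than `2 * span_s` the two spans overlap;
#' the `spans_overlap` flag reports it.
#'
#' @param frames An emotion-frame tibble.
#' @param span_s Span length in seconds (default 300 = 5 minutes).
#' @param which `"both"` (default), `"first"` or `"last"`.
#' @return A tibble with one row per stream and segment: `segment`
#'   (`first`/`last`), the 7 channel means, `n_frames`, `spans_overlap`,
#'   and `scope`.
#' @export
boundary_emotion_average <- function(frames, span_s = 300,
                                     which = c("both", "first", "last")) {
  which <- match.arg(which)
  check_frames(frames)
  stopifnot(span_s >= 1)
  segs <- if (which == "both") c("first", "last") else which
  frames %>%
    group_by(.data$stream_id) %>%
    dplyr::group_modify(function(df, key) {
      t0 <- min(df$t)
      t1 <- max(df$t)
      overlap <- (t1 - t0 + 1) < 2 * span_s
      purrr::map_dfr(segs, function(seg) {
        w <- if (seg == "first") df[df$t <= t0 + span_s - 1, ] else df[df$t >= t1 - span_s + 1, ]
        means <- vapply(EMOTIONS, function(ch) mean(w[[ch]]), numeric(1))
        tibble(
          segment = seg, !!!as.list(means), n_frames = nrow(w),
          spans_overlap = overlap,
          scope = paste0("boundary_", seg, "5")
        )
      })
    }) %>%
    ungroup()
}

#' Period-wide emotion average
#'
#' Pools every frame in the supplied period (e.g. all streams of the last
#' two weeks) and reports the mean of each channel — the numbers behind the
#' emotion pie chart. Pooling weights each stream by its frame count.
#'
#' @param frames An emotion-frame tibble, already restricted to the period.
#' @return A one-row tibble: the 7 channel means, `n_frames`,
#'   `scope = "period"`.
#' @export
period_emotion_average <- function(frames) {
  check_frames(frames)
  if (nrow(frames) == 0) {
    abort("No frames in the period.")
  }
  means <- vapply(EMOTIONS, function(ch) mean(frames[[ch]]), numeric(1))
  tibble(!!!as.list(means), n_frames = nrow(frames), scope = "period")
}
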