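test_that("trailing-median smoothing is exact against the brute-force oracle", {
  set.seed(17)
  # constant stream is a fixed point
  const <- random_frames(1)[rep(1, 50), ] %>% dplyr::mutate(t = 0:49)
  expect_equal(
    as.data.frame(smooth_stream(const)[, emotion_channels()]),
    as.data.frame(const[, emotion_channels()])
  )

  # a single one-second spike in a constant channel disappears
  spike <- const
  spike$angry[25] <- spike$angry[25] + 40
  sm <- smooth_stream(spike)
  expect_equal(sm$angry[28:35], const$angry[28:35])
  expect_lt(max(sm$angry), max(spike$angry))

  # random streams, with and without missing seconds
  for (i in 1:5) {
    f <- random_frames(100, drop = sample(c(0, 10), 1))
    expect_equal(
      as.data.frame(smooth_stream(f)[, emotion_channels()]),
      as.data.frame(oracle_smooth(f)[, emotion_channels()])
    )
  }
})

test_that("smoothing never leaves the observed channel range", {
  set.seed(18)
  for (i in 1:10) {
    f <- random_frames(80)
    sm <- smooth_stream(f)
    for (ch in emotion_channels()) {
      expect_true(all(sm[[ch]] >= min(f[[ch]]) - 1e-12))
      expect_true(all(sm[[ch]] <= max(f[[ch]]) + 1e-12))
    }
  }
})

test_that("per-event medians use the inclusive +-3 s window, truncated at bounds", {
  set.seed(19)
  f <- random_frames(60)
  ev <- tibble::tibble(stream_id = "v1", t = c(0L, 10L, 30L), kind = "kill")
  med <- event_emotion_medians(f, ev)
  expect_equal(med$n_frames, c(4L, 7L, 7L)) # window at t=0 truncates to [0,3]
  for (i in seq_len(nrow(ev))) {
    expect_equal(
      as.numeric(med[i, emotion_channels()]),
      unname(oracle_event_median(f, ev$t[i])),
      tolerance = 1e-12
    )
  }

  const <- random_frames(1)[rep(1, 20), ] %>% dplyr::mutate(t = 0:19)
  m1 <- event_emotion_medians(const, tibble::tibble(stream_id = "v1", t = 10L, kind = "death"))
  expect_equal(as.numeric(m1[1, emotion_channels()]),
               as.numeric(const[1, emotion_channels()]))

  expect_error(
    event_emotion_medians(f, tibble::tibble(stream_id = "v1", t = 500L, kind = "kill")),
    "t=500"
  )
})

test_that("event-kind aggregation is a median of per-event medians", {
  set.seed(20)
  f <- random_frames(200)
  ev <- tibble::tibble(stream_id = "v1", t = c(50L, 150L), kind = "death")
  per <- event_emotion_medians(f, ev)
  agg <- aggregate_event_medians(f, ev)
  death_row <- agg[agg$kind == "death", ]
  # median of two per-event medians is their mean
  expect_equal(
    as.numeric(death_row[1, emotion_channels()]),
    as.numeric((per[1, emotion_channels()] + per[2, emotion_channels()]) / 2)
  )
  expect_equal(death_row$n_events, 2L)
  # single event: aggregation equals that event's median
  one <- aggregate_event_medians(f, ev[1, ])
  expect_equal(
    as.numeric(one[one$kind == "death", emotion_channels()]),
    as.numeric(per[1, emotion_channels()])
  )
  # absent kinds get an all-NA row
  expect_true(all(is.na(agg[agg$kind == "kill", emotion_channels()])))
  expect_equal(agg$n_events[agg$kind == "kill"], 0L)
})

test_that("match averages equal brute-force column means and sum to 100", {
  set.seed(21)
  f <- random_frames(300)
  avg <- match_emotion_average(f)
  expect_equal(
    as.numeric(avg[1, emotion_channels()]),
    unname(colMeans(as.matrix(f[, emotion_channels()])))
  )
  expect_equal(sum(avg[1, emotion_channels()]), 100, tolerance = 1e-6)

  two <- tibble::tibble(
    stream_id = "v1", t = 0:1,
    angry = c(100, 0), disgust = 0, fear = 0, happy = c(0, 100),
    sad = 0, surprise = 0, neutral = 0
  )
  avg2 <- match_emotion_average(two)
  expect_equal(avg2$angry, 50)
  expect_equal(avg2$happy, 50)
})

test_that("boundary averages contrast the first and last five minutes", {
  const <- random_frames(1)[rep(1, 600), ] %>% dplyr::mutate(t = 0:599)
  b <- boundary_emotion_average(const)
  expect_equal(
    as.numeric(b[b$segment == "first", emotion_channels()]),
    as.numeric(b[b$segment == "last", emotion_channels()])
  )
  expect_false(any(b$spans_overlap))

  # anger ramping up -> last five minutes angrier than the first
  n <- 720
  ramp <- tibble::tibble(
    stream_id = "v1", t = 0:(n - 1),
    angry = seq(5, 45, length.out = n)
  )
  ramp$neutral <- 100 - ramp$angry
  for (ch in c("disgust", "fear", "happy", "sad", "surprise")) ramp[[ch]] <- 0
  rb <- boundary_emotion_average(ramp)
  expect_gt(rb$angry[rb$segment == "last"], rb$angry[rb$segment == "first"])

  # 400-second match: spans overlap for 200 s and the flag says so
  short <- random_frames(400)
  sb <- boundary_emotion_average(short)
  expect_true(all(sb$spans_overlap))
  expect_equal(sb$n_frames, c(300L, 300L))
})

test_that("period averages pool frames weighted by stream length", {
  set.seed(22)
  f1 <- random_frames(100, stream_id = "v1")
  f2 <- random_frames(50, stream_id = "v2")
  both <- dplyr::bind_rows(f1, f2)
  pe <- period_emotion_average(both)
  manual <- (colMeans(as.matrix(f1[, emotion_channels()])) * 100 +
    colMeans(as.matrix(f2[, emotion_channels()])) * 50) / 150
  expect_equal(as.numeric(pe[1, emotion_channels()]), unname(manual))
  expect_equal(sum(pe[1, emotion_channels()]), 100, tolerance = 1e-6)
  expect_equal(pe$n_frames, 150L)
  expect_error(period_emotion_average(f1[0, ]), "No frames")
})
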