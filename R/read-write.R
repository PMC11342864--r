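#' Read a match history
#'
#' Reads one-row-per-match telemetry records from CSV or JSONL (one JSON
#' object per line, FACEIT-style payload keys). Timestamps are parsed as
#' ISO-8601 and stored in UTC; rows come back sorted by `started_at`.
#'
#' Expected columns/keys: `match_id, gamer_id, started_at, finished_at,
#' kills, deaths, assists` (the in-game stat columns are optional; extra
#' columns are passed through untouched).
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"jsonl"`; guessed from the file extension when
#'   omitted.
#' @return A tibble of matches sorted by `started_at`, timestamps in UTC,
#'   with a `duration_min` column added.
#' @export
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "match_id,gamer_id,started_at,finished_at,kills,deaths,assists",
#'   "m2,g1,2021-03-01T21:00:00Z,2021-03-01T21:40:00Z,15,12,3",
#'   "m1,g1,2021-03-01T20:00:00Z,2021-03-01T20:38:00Z,20,14,5"
#' ), csv)
#' read_matches(csv)
read_matches <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (!file.exists(path)) abort(paste0("File not found: ", path))

  if (format == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    raw <- as_tibble(raw)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    raw <- purrr::map_dfr(lines, function(l) {
      as_tibble(lapply(jsonlite::fromJSON(l, simplifyVector = TRUE), as.character))
    })
  }
  cols <- c("match_id", "gamer_id", "started_at", "finished_at")
  if (nrow(raw) == 0) {
    return(tibble(
      match_id = character(), gamer_id = character(),
      started_at = as.POSIXct(character(), tz = "UTC"),
      finished_at = as.POSIXct(character(), tz = "UTC"),
      kills = integer(), deaths = integer(), assists = integer(),
      duration_min = numeric()
    ))
  }
  missing <- setdiff(cols, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Match file is missing column(s): ", paste(missing, collapse = ", ")))
  }

  parse_ts <- function(x, col) {
    out <- lubridate::ymd_hms(x, tz = "UTC", quiet = TRUE)
    bad <- which(is.na(out) & !is.na(x) & nzchar(x))
    if (length(bad) > 0) {
      abort(paste0(
        "Malformed ", col, " timestamp in row ", bad[1],
        ": '", x[bad[1]], "' (expected ISO-8601)."
      ))
    }
    out
  }
  matches <- raw %>%
    mutate(
      started_at = parse_ts(.data$started_at, "started_at"),
      finished_at = parse_ts(.data$finished_at, "finished_at"),
      across(any_of(c("kills", "deaths", "assists")), ~ as.integer(.x))
    )

  dup <- matches$match_id[duplicated(matches$match_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate match_id: ", paste(unique(dup), collapse = ", ")))
  }
  bad_span <- matches$finished_at <= matches$started_at
  if (any(bad_span)) {
    abort(paste0(
      "finished_at is not after started_at for match_id: ",
      paste(matches$match_id[bad_span], collapse = ", ")
    ))
  }
  matches %>%
    mutate(duration_min = secs_between(.data$started_at, .data$finished_at) / 60) %>%
    arrange(.data$started_at)
}

#' Write a match history
#'
#' Inverse of [read_matches()]: writes the documented CSV dialect
#' (RFC-4180, UTF-8, ISO-8601 UTC timestamps) or JSONL with one match
#' object per line.
#'
#' @param matches A matches tibble.
#' @param path Output path.
#' @inheritParams read_matches
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  check_matches(matches)
  out <- matches %>%
    select(-any_of("duration_min")) %>%
    mutate(
      started_at = format_utc(.data$started_at),
      finished_at = format_utc(.data$finished_at)
    )
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    lines <- vapply(
      seq_len(nrow(out)),
      function(i) jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE, digits = NA),
      character(1)
    )
    writeLines(lines, path)
  }
  invisible(path)
}

format_utc <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Read a per-second emotion stream
#'
#' Reads per-second facial-emotion percentages (columns `stream_id, t,
#' angry, disgust, fear, happy, sad, surprise, neutral`). Each row is
#' normalized so the seven channels sum to 100 (recognition backends often
#' emit unnormalized scores). Seconds may be missing inside a stream; the
#' gaps are counted and attached as the `"gaps"` attribute.
#'
#' @param path Path to the CSV file.
#' @return A tibble of frames, `t` strictly increasing within each
#'   `stream_id`, each row summing to 100. Attribute `gaps`: tibble with
#'   per-stream counts of missing interior seconds.
#' @export
read_emotion_stream <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  check_frames(raw)
  raw$t <- as.integer(raw$t)
  normalize_frames(raw)
}

# Normalize the 7 emotion channels of each row to sum to 100; validate.
normalize_frames <- function(frames) {
  check_frames(frames)
  if (nrow(frames) == 0) {
    attr(frames, "gaps") <- tibble(stream_id = character(), n_missing_seconds = integer())
    return(frames)
  }
  vals <- as.matrix(frames[, EMOTIONS])
  if (any(vals < 0)) {
    abort(paste0("Negative emotion value in row ", which(rowSums(vals < 0) > 0)[1], "."))
  }
  totals <- rowSums(vals)
  if (any(totals == 0)) {
    abort(paste0(
      "All-zero emotion row (cannot normalize) at row ",
      which(totals == 0)[1], "."
    ))
  }
  if (any(frames$t < 0)) abort("Frame times `t` must be nonnegative.")
  frames <- arrange(frames, .data$stream_id, .data$t)
  if (anyDuplicated(frames[, c("stream_id", "t")]) > 0) {
    abort("Frame times `t` must be strictly increasing within a stream.")
  }
  vals <- as.matrix(frames[, EMOTIONS])
  frames[, EMOTIONS] <- as_tibble(sweep(vals, 1, rowSums(vals), "/") * 100)
  gaps <- frames %>%
    group_by(.data$stream_id) %>%
    summarise(
      n_missing_seconds = as.integer(max(.data$t) - min(.data$t) + 1L - n()),
      .groups = "drop"
    )
  attr(frames, "gaps") <- gaps
  frames
}

#' Write a per-second emotion stream
#'
#' @param frames An emotion-frame tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_emotion_stream <- function(frames, path) {
  check_frames(frames)
  utils::write.csv(
    frames[, c("stream_id", "t", EMOTIONS)], path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read an in-game event log
#'
#' Events are timestamped in stream-relative seconds, one of `kill`,
#' `death`, `round_start`, `round_end` (columns `stream_id, t, kind`).
#'
#' @param path Path to the CSV file.
#' @return A tibble of events sorted by `stream_id`, `t`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  ev <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  required <- c("stream_id", "t", "kind")
  missing <- setdiff(required, names(ev))
  if (length(missing) > 0) {
    abort(paste0("Event file is missing column(s): ", paste(missing, collapse = ", ")))
  }
  valid <- c("kill", "death", "round_start", "round_end")
  bad <- setdiff(unique(ev$kind), valid)
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown event kind(s): ", paste(bad, collapse = ", "),
      " (valid: ", paste(valid, collapse = ", "), ")."
    ))
  }
  ev$t <- as.integer(ev$t)
  arrange(ev, .data$stream_id, .data$t)
}

#' Write an in-game event log
#'
#' @param events An events tibble (`stream_id, t, kind`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(
    events[, c("stream_id", "t", "kind")], path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a stream-to-match mapping
#'
#' Video-derived emotion streams carry their own relative clock; this sidecar
#' table (`stream_id, match_id, offset_s`) declares which match each stream
#' belongs to and the offset (seconds) of stream time 0 from the match start.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `stream_id`, `match_id`, `offset_s`.
#' @export
read_stream_map <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  m <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  required <- c("stream_id", "match_id", "offset_s")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    abort(paste0("Stream map is missing column(s): ", paste(missing, collapse = ", ")))
  }
  m$offset_s <- as.integer(m$offset_s)
  m
}
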