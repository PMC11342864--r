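#' Write a report to schema-versioned JSON
#'
#' Serializes a [historical_stats()], [recent_stats()] or emotion-summary
#' result to a stable JSON document (`gametel/report@1`). Undefined values
#' are written as explicit `null`s, never dropped, and two writes of the
#' same report are byte-identical; [read_report()] restores a structurally
#' equal object.
#'
#' @param report A `gametel_historical`, `gametel_recent`, or an
#'   emotion-summary tibble (any output of the emotion analytics functions
#'   carrying a `scope` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- list(schema = "gametel/report@1", body = report_to_list(report))
  json <- jsonlite::toJSON(
    payload,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null",
    dataframe = "columns", pretty = TRUE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path Path to a `gametel/report@1` JSON file.
#' @return The restored report object.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(payload$schema, "gametel/report@1")) {
    abort("Not a gametel report (missing schema 'gametel/report@1').")
  }
  report_from_list(payload$body)
}

na_null <- function(x) if (length(x) == 0 || (length(x) == 1 && is.na(x))) NA else x

report_to_list <- function(report) {
  if (inherits(report, "gametel_historical")) {
    out <- unclass(report)
    out$period <- list(from = as.character(out$period$from), to = as.character(out$period$to))
    out$by_month <- as.list(out$by_month)
    out
  } else if (inherits(report, "gametel_recent")) {
    out <- unclass(report)
    out$as_of <- format_utc(out$as_of)
    ds <- out$daily_series
    ds$day <- as.character(ds$day)
    out$daily_series <- as.list(ds)
    out
  } else if (is.data.frame(report) && "scope" %in% names(report)) {
    list(type = "emotion_summary", data = as.list(report))
  } else {
    abort("Unsupported report object.")
  }
}

report_from_list <- function(body) {
  scal <- function(x) if (is.null(x)) NA else x
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  int <- function(x) if (is.null(x)) NA_integer_ else as.integer(x)
  relist_tbl <- function(cols) as_tibble(lapply(cols, unlist_nulls))

  if (identical(body$type, "historical")) {
    body$period <- list(from = as_date(body$period$from), to = as_date(body$period$to))
    for (blk in c("general", "session_stats", "monthly", "weekly")) {
      body[[blk]] <- lapply(body[[blk]], scal)
    }
    body$general$n_matches <- int(body$general$n_matches)
    body$general$n_sessions <- int(body$general$n_sessions)
    body$monthly$n_active_months <- int(body$monthly$n_active_months)
    body$weekly$n_weeks_played <- int(body$weekly$n_weeks_played)
    body$day_part <- lapply(body$day_part, function(b) lapply(b, num))
    body$weekday <- lapply(body$weekday, function(b) lapply(b, num))
    bm <- relist_tbl(body$by_month)
    for (cc in c("n_matches", "n_sessions", "matches_midweek", "matches_weekend")) {
      bm[[cc]] <- as.integer(bm[[cc]])
    }
    body$by_month <- bm
    structure(body, class = "gametel_historical")
  } else if (identical(body$type, "recent")) {
    body$as_of <- lubridate::ymd_hms(body$as_of, tz = "UTC")
    for (f in c("total_hours_last_7d", "hours_per_session_last_7d")) body[[f]] <- num(body[[f]])
    for (f in c(
      "pct_diff_hours_vs_prev_week", "pct_diff_hours_vs_prev_month",
      "pct_diff_hps_vs_prev_week", "pct_diff_hps_vs_prev_month",
      "total_sessions_last_7d"
    )) {
      body[[f]] <- int(body[[f]])
    }
    ds <- relist_tbl(body$daily_series)
    ds$day <- as_date(ds$day)
    ds$n_matches <- as.integer(ds$n_matches)
    ds$n_sessions <- as.integer(ds$n_sessions)
    body$daily_series <- ds
    structure(body, class = "gametel_recent")
  } else if (identical(body$type, "emotion_summary")) {
    tb <- relist_tbl(body$data)
    for (cc in intersect(c(EMOTIONS, "n_frames", "n_events", "t"), names(tb))) {
      tb[[cc]] <- if (cc %in% c("n_frames", "n_events", "t")) as.integer(tb[[cc]]) else as.numeric(tb[[cc]])
    }
    tb
  } else {
    abort(paste0("Unknown report type: ", body$type %||% "<missing>"))
  }
}

# unlist a column that may contain NULLs (JSON nulls) -> NA-preserving vector
unlist_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x[vapply(x, is.null, logical(1))] <- NA
  unlist(x)
}
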