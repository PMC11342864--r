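CHART_KINDS <- c(
  "monthly_daypart_bars", "monthly_weekday_bars", "monthly_by_year_bars",
  "matches_vs_sessions_bars", "daily_matches_vs_sessions",
  "emotion_stacked_by_match", "emotion_boundary_bars", "emotion_pie"
)

#' Build chart data from computed report blocks
#'
#' Turns a report object into a deterministic, numbers-only chart
#' specification (the chart layer never recomputes anything from raw
#' telemetry). Series that are zero everywhere are omitted, matching the
#' reporting convention of leaving e.g. negligible morning hours off the
#' monthly bars.
#'
#' Available kinds and the inputs they accept:
#'
#' * `monthly_daypart_bars`, `monthly_weekday_bars`, `monthly_by_year_bars`,
#'   `matches_vs_sessions_bars` — a [historical_stats()] object.
#' * `daily_matches_vs_sessions` — a [recent_stats()] object.
#' * `emotion_stacked_by_match` — output of [match_emotion_average()].
#' * `emotion_boundary_bars` — output of [boundary_emotion_average()].
#' * `emotion_pie` — output of [period_emotion_average()].
#'
#' @param x A report object (see above).
#' @param kind One of the kinds listed above.
#' @return An object of class `gametel_chart`: `kind`, `title`, and a long
#'   `series` tibble (`label`, `series`, `value`).
#' @seealso [render_chart()], [ggplot2::autoplot()]
#' @export
build_chart_data <- function(x, kind) {
  if (!kind %in% CHART_KINDS) {
    abort(paste0(
      "Unknown chart kind '", kind, "'. Valid kinds: ",
      paste(CHART_KINDS, collapse = ", "), "."
    ))
  }
  series <- switch(kind,
    monthly_daypart_bars = {
      stopifnot(inherits(x, "gametel_historical"))
      x$by_month %>%
        select("month", morning = "hours_morning", afternoon = "hours_afternoon",
               evening = "hours_evening") %>%
        tidyr::pivot_longer(-"month", names_to = "series", values_to = "value") %>%
        rename(label = "month")
    },
    monthly_weekday_bars = {
      stopifnot(inherits(x, "gametel_historical"))
      x$by_month %>%
        select("month", midweek = "hours_midweek", weekend = "hours_weekend") %>%
        tidyr::pivot_longer(-"month", names_to = "series", values_to = "value") %>%
        rename(label = "month")
    },
    monthly_by_year_bars = {
      stopifnot(inherits(x, "gametel_historical"))
      x$by_month %>%
        mutate(
          label = substr(.data$month, 6, 7),
          series = substr(.data$month, 1, 4)
        ) %>%
        group_by(.data$label, .data$series) %>%
        summarise(value = sum(.data$played_hours), .groups = "drop")
    },
    matches_vs_sessions_bars = {
      stopifnot(inherits(x, "gametel_historical"))
      x$by_month %>%
        select("month", matches = "n_matches", sessions = "n_sessions") %>%
        tidyr::pivot_longer(-"month", names_to = "series", values_to = "value") %>%
        rename(label = "month")
    },
    daily_matches_vs_sessions = {
      stopifnot(inherits(x, "gametel_recent"))
      x$daily_series %>%
        mutate(label = as.character(.data$day)) %>%
        select("label", matches = "n_matches", sessions = "n_sessions") %>%
        tidyr::pivot_longer(-"label", names_to = "series", values_to = "value")
    },
    emotion_stacked_by_match = emotion_long(x, "stream_id"),
    emotion_boundary_bars = {
      stopifnot(is.data.frame(x), "segment" %in% names(x))
      x %>%
        mutate(label = paste(.data$stream_id, .data$segment, sep = ":")) %>%
        select("label", all_of(EMOTIONS)) %>%
        tidyr::pivot_longer(-"label", names_to = "series", values_to = "value")
    },
    emotion_pie = {
      stopifnot(is.data.frame(x), nrow(x) == 1)
      tibble(
        label = EMOTIONS,
        series = "period",
        value = as.numeric(x[1, EMOTIONS])
      )
    }
  )
  # drop series that are zero (or NA) everywhere
  keep <- series %>%
    group_by(.data$series) %>%
    summarise(any_signal = any(!is.na(.data$value) & .data$value != 0), .groups = "drop")
  series <- series %>%
    left_join(keep, by = "series") %>%
    filter(.data$any_signal | kind == "emotion_pie") %>%
    select("label", "series", "value")
  if (any(!is.finite(series$value) & !is.na(series$value))) {
    abort("Chart series contain non-finite values.")
  }
  structure(
    list(kind = kind, title = gsub("_", " ", kind), series = series),
    class = "gametel_chart"
  )
}

emotion_long <- function(x, id_col) {
  stopifnot(is.data.frame(x), id_col %in% names(x))
  x %>%
    mutate(label = .data[[id_col]]) %>%
    select("label", all_of(EMOTIONS)) %>%
    tidyr::pivot_longer(-"label", names_to = "series", values_to = "value")
}

#' Render a chart specification to disk
#'
#' JSON export is byte-stable across runs (assert on numbers, not pixels);
#' SVG/PNG rendering goes through the [ggplot2::autoplot()] method.
#'
#' @param chart A `gametel_chart` from [build_chart_data()].
#' @param path Output path.
#' @param format `"json"`, `"svg"` or `"png"` (guessed from the extension
#'   when omitted).
#' @param width,height Device size in inches for raster/vector output.
#' @return `path`, invisibly.
#' @export
render_chart <- function(chart, path, format = c("auto", "json", "svg", "png"),
                         width = 8, height = 5) {
  stopifnot(inherits(chart, "gametel_chart"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("json", "svg", "png")) {
      abort("Cannot guess format from extension; pass `format` explicitly.")
    }
  }
  if (chart$kind == "emotion_pie" &&
      (nrow(chart$series) == 0 || all(is.na(chart$series$value)) ||
         sum(chart$series$value, na.rm = TRUE) == 0)) {
    abort("Nothing to plot: the emotion pie has an all-zero series.")
  }
  if (format == "json") {
    json <- jsonlite::toJSON(
      list(
        schema = "gametel/chart@1", kind = chart$kind, title = chart$title,
        series = as.list(chart$series)
      ),
      auto_unbox = TRUE, digits = NA, null = "null", na = "null",
      dataframe = "columns", pretty = TRUE
    )
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(json, con, sep = "\n", useBytes = TRUE)
  } else {
    ggplot2::ggsave(path, plot = ggplot2::autoplot(chart), width = width,
                    height = height, device = format)
  }
  invisible(path)
}

#' Read a chart specification written by [render_chart()]
#'
#' @param path Path to a `gametel/chart@1` JSON file.
#' @return A `gametel_chart` object equal to the one written.
#' @export
read_chart <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(payload$schema, "gametel/chart@1")) {
    abort("Not a gametel chart (missing schema 'gametel/chart@1').")
  }
  series <- as_tibble(lapply(payload$series, unlist_nulls))
  series$value <- as.numeric(series$value)
  structure(
    list(kind = payload$kind, title = payload$title, series = series),
    class = "gametel_chart"
  )
}

#' Plot a chart specification
#'
#' @param object A `gametel_chart`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gametel_chart
#' @export
autoplot.gametel_chart <- function(object, ...) {
  s <- object$series
  if (object$kind == "emotion_pie") {
    p <- ggplot2::ggplot(s, ggplot2::aes(x = "", y = .data$value, fill = .data$label)) +
      ggplot2::geom_col(width = 1) +
      ggplot2::coord_polar(theta = "y") +
      ggplot2::labs(title = object$title, fill = "emotion", x = NULL, y = NULL) +
      ggplot2::theme_void()
    return(p)
  }
  stacked <- object$kind %in% c("emotion_stacked_by_match", "emotion_boundary_bars")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$label, y = .data$value, fill = .data$series)) +
    ggplot2::geom_col(position = if (stacked) "stack" else ggplot2::position_dodge()) +
    ggplot2::labs(title = object$title, x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
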