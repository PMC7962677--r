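#' Display geometry
#'
#' Screen geometry needed to convert pixel coordinates into degrees of
#' visual angle.
#'
#' @param resolution Screen resolution in pixels, `c(width, height)`.
#' @param physical_size Physical screen size in mm, `c(width, height)`.
#' @param viewing_distance Eye-to-screen distance in mm.
#' @return An object of class `"display_geometry"`.
#' @export
#' @examples
#' display_geometry(c(1024, 768), c(376, 301), 650)
display_geometry <- function(resolution, physical_size, viewing_distance) {
  if (length(resolution) != 2L || any(!is.finite(resolution)) ||
      any(resolution <= 0)) {
    stopf("field 'resolution' must be two positive numbers",
          class = "microsacc_validation_error")
  }
  if (length(physical_size) != 2L || any(!is.finite(physical_size)) ||
      any(physical_size <= 0)) {
    stopf("field 'physical_size' must be two positive numbers",
          class = "microsacc_validation_error")
  }
  check_number(viewing_distance, "viewing_distance", lower = 0,
               allow_equal_lower = FALSE)
  structure(list(resolution = as.numeric(resolution),
                 physical_size = as.numeric(physical_size),
                 viewing_distance = as.numeric(viewing_distance)),
            class = "display_geometry")
}

#' Convert pixel coordinates to degrees of visual angle
#'
#' Positions are recentered on the screen center and converted with a
#' per-axis arctangent of the physical offset over the viewing distance
#' (exact, not the small-angle approximation). x is positive rightward and
#' y positive upward (screen pixel rows increase downward).
#'
#' @param x_px,y_px Pixel coordinates (vectors of equal length).
#' @param geometry A [display_geometry()].
#' @return A list with numeric vectors `x_deg` and `y_deg`.
#' @export
pixels_to_degrees <- function(x_px, y_px, geometry) {
  stopifnot(inherits(geometry, "display_geometry"))
  if (length(x_px) != length(y_px)) {
    stopf("x_px and y_px must have equal length",
          class = "microsacc_validation_error")
  }
  mm_per_px <- geometry$physical_size / geometry$resolution
  x_mm <- (x_px - geometry$resolution[1] / 2) * mm_per_px[1]
  y_mm <- (geometry$resolution[2] / 2 - y_px) * mm_per_px[2]
  list(x_deg = atan2(x_mm, geometry$viewing_distance) * 180 / pi,
       y_deg = atan2(y_mm, geometry$viewing_distance) * 180 / pi)
}

samples_columns <- c("participant_id", "session", "trial_index", "t",
                     "xl", "yl", "xr", "yr", "valid_l", "valid_r")
events_columns <- c("participant_id", "session", "trial_index", "eye",
                    "onset_idx", "offset_idx", "duration_ms",
                    "peak_velocity_dps", "amplitude_deg", "dx_deg", "dy_deg")

#' Read a gaze samples table
#'
#' Reads the tab-separated samples interchange format (columns
#' `participant_id, session, trial_index, t, xl, yl, xr, yr, valid_l,
#' valid_r`; `t` in seconds, positions in degrees — or in pixels if a
#' `geometry` is supplied, in which case they are converted). Rows are
#' grouped into trials by (participant, session, trial) and sorted by time
#' within trial. A malformed or missing numeric position cell marks that
#' sample invalid for the affected eye.
#'
#' @param path Path to a TSV file.
#' @param sampling_rate Sampling rate in Hz of the recordings.
#' @param geometry Optional [display_geometry()]; if given, positions are
#'   interpreted as pixels and converted to degrees.
#' @return A [gaze_study()] (possibly with zero trials for a header-only
#'   file, returned as an empty list of trials).
#' @export
read_samples_table <- function(path, sampling_rate, geometry = NULL) {
  if (!file.exists(path)) {
    stopf("samples file '%s' does not exist", path,
          class = "microsacc_io_error")
  }
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  missing <- setdiff(samples_columns, names(raw))
  if (length(missing)) {
    stopf("samples table is missing mandatory column(s): %s",
          paste(missing, collapse = ", "), class = "microsacc_schema_error")
  }
  if (nrow(raw) == 0L) {
    return(structure(list(trials = list()), class = "gaze_study"))
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  raw$t <- num(raw$t)
  for (cc in c("xl", "yl", "xr", "yr")) raw[[cc]] <- num(raw[[cc]])
  raw$valid_l <- parse_flag(raw$valid_l)
  raw$valid_r <- parse_flag(raw$valid_r)
  key <- paste(raw$participant_id, raw$session, raw$trial_index)
  groups <- split(seq_len(nrow(raw)), key)
  # canonical order: participant, session (pre before post), trial index
  first <- vapply(groups, `[[`, 1L, 1L)
  ord <- order(raw$participant_id[first],
               match(raw$session[first], c("pre", "post")),
               as.integer(raw$trial_index[first]))
  trials <- lapply(groups[ord], function(rows) {
    g <- raw[rows, , drop = FALSE]
    g <- g[order(g$t), , drop = FALSE]
    xl <- g$xl; yl <- g$yl; xr <- g$xr; yr <- g$yr
    if (!is.null(geometry)) {
      l <- pixels_to_degrees(xl, yl, geometry)
      r <- pixels_to_degrees(xr, yr, geometry)
      xl <- l$x_deg; yl <- l$y_deg; xr <- r$x_deg; yr <- r$y_deg
    }
    gaze_trial(g$participant_id[1], g$session[1],
               as.integer(g$trial_index[1]), sampling_rate,
               xl = xl, yl = yl, xr = xr, yr = yr, time = g$t,
               valid_l = g$valid_l, valid_r = g$valid_r)
  })
  names(trials) <- NULL
  gaze_study(trials)
}

parse_flag <- function(v) {
  out <- toupper(trimws(v)) %in% c("TRUE", "T", "1")
  out
}

#' Write a gaze samples table
#'
#' Inverse of [read_samples_table()]: serializes a study (or list of trials)
#' to the tab-separated samples format, positions in degrees.
#'
#' @param study A [gaze_study()] or list of [gaze_trial()] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_samples_table <- function(study, path) {
  trials <- if (inherits(study, "gaze_study")) study$trials else study
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(samples_columns, collapse = "\t"), con)
  for (tr in trials) {
    df <- data.frame(participant_id = tr$participant_id,
                     session = tr$session, trial_index = tr$trial_index,
                     t = fmt_num(tr$time),
                     xl = fmt_num(tr$xl), yl = fmt_num(tr$yl),
                     xr = fmt_num(tr$xr), yr = fmt_num(tr$yr),
                     valid_l = tr$valid_l, valid_r = tr$valid_r)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write / read a microsaccade events table
#'
#' Tab-separated events format with columns `participant_id, session,
#' trial_index, eye (L/R/BIN), onset_idx, offset_idx, duration_ms,
#' peak_velocity_dps, amplitude_deg, dx_deg, dy_deg`. Sample indices are
#' 0-based inclusive. Numeric fields are written at full double precision so
#' a write/read round trip reproduces the events exactly.
#'
#' @param events A data frame with the columns above.
#' @param path File path.
#' @return `write_events_table()` returns the path invisibly;
#'   `read_events_table()` returns the events data frame.
#' @export
write_events_table <- function(events, path) {
  missing <- setdiff(events_columns, names(events))
  if (length(missing)) {
    stopf("events table is missing column(s): %s",
          paste(missing, collapse = ", "), class = "microsacc_schema_error")
  }
  write_tsv_exact(events[, events_columns, drop = FALSE], path)
}

#' @rdname write_events_table
#' @export
read_events_table <- function(path) {
  if (!file.exists(path)) {
    stopf("events file '%s' does not exist", path,
          class = "microsacc_io_error")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(events_columns, names(df))
  if (length(missing)) {
    stopf("events table is missing column(s): %s",
          paste(missing, collapse = ", "), class = "microsacc_schema_error")
  }
  df$trial_index <- as.integer(df$trial_index)
  df$onset_idx <- as.integer(df$onset_idx)
  df$offset_idx <- as.integer(df$offset_idx)
  df
}

#' Write a key-value summary document
#'
#' Flattens a named list (recursively, with dotted keys) into a two-column
#' tab-separated `key<TAB>value` text document.
#'
#' @param results A named list of scalars (or nested named lists).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_summary <- function(results, path) {
  flat <- flatten_kv(results)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(flat)) {
    v <- flat[[k]]
    v <- if (is.numeric(v)) paste(fmt_num(v), collapse = ",")
         else paste(as.character(v), collapse = ",")
    writeLines(paste(k, v, sep = "\t"), con)
  }
  invisible(path)
}

flatten_kv <- function(x, prefix = NULL) {
  out <- list()
  for (k in names(x)) {
    key <- if (is.null(prefix)) k else paste(prefix, k, sep = ".")
    v <- x[[k]]
    if (is.list(v) && !is.data.frame(v)) {
      out <- c(out, flatten_kv(v, key))
    } else if (!is.data.frame(v)) {
      out[[key]] <- v
    }
  }
  out
}
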