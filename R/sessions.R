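#' @rdname read_sessions
#' @format NULL
#' @export
session_columns <- c("hand_id", "group", "side", "severity", "lap",
                     "direction", "collected", "t", "x", "y")

sessions_geometry <- function(sessions) {
  g <- attr(sessions, "geometry", exact = TRUE)
  if (is.null(g)) task_geometry() else g
}

#' Build a sessions table from a data frame
#'
#' A sessions object is a tidy tibble with one row per recorded thumb
#' position. A *trial* is one outward reach (hand, lap, direction); a
#' *session* is one hand's two measurement laps of 12 directions each.
#' Coordinates are in cm with the origin at the circle center, x rightward
#' and y upward; `t` is seconds since trial start.
#'
#' @param data A data frame with the columns listed in [session_columns].
#' @param geometry The [task_geometry()] the data were recorded under.
#' @param validate Run [validate_sessions()] on the result.
#' @return A `cts_sessions` tibble carrying `geometry` as an attribute.
#' @export
as_sessions <- function(data, geometry = task_geometry(), validate = TRUE) {
  missing_cols <- setdiff(session_columns, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required session columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "opposcreen_format_error")
  }
  data <- tibble::as_tibble(data)[session_columns]
  data$hand_id   <- as.character(data$hand_id)
  data$group     <- as.character(data$group)
  data$side      <- as.character(data$side)
  data$severity  <- as.integer(data$severity)
  data$lap       <- as.integer(data$lap)
  data$direction <- as.integer(data$direction)
  data$collected <- as.logical(data$collected)
  data$t <- as.double(data$t)
  data$x <- as.double(data$x)
  data$y <- as.double(data$y)
  out <- structure(data, class = c("cts_sessions", class(tibble::tibble())),
                   geometry = geometry)
  if (validate) validate_sessions(out)
  out
}

#' Validate a sessions table
#'
#' Checks the structural invariants of session data: group/side labels are
#' known, directions lie in range, timestamps within a trial are strictly
#' increasing and non-negative (a duplicated (lap, direction) trial shows up
#' as a timestamp reset and is reported as such), the `collected` flag is
#' constant within a trial, collected trials end within `tol` cm of the
#' target circle and within the timeout. Failures name the offending hand
#' and direction.
#'
#' @param sessions A `cts_sessions` tibble (see [as_sessions()]).
#' @param tol Tolerance in cm for the final-sample-on-circle check.
#' @return `sessions`, invisibly.
#' @export
validate_sessions <- function(sessions, tol = 0.1) {
  g <- sessions_geometry(sessions)
  if (nrow(sessions) == 0) return(invisible(sessions))

  bad_group <- setdiff(unique(sessions$group), c("healthy", "cts", "unknown"))
  if (length(bad_group) > 0) {
    abort(paste0("Unknown group label(s): ", paste(bad_group, collapse = ", ")),
          class = "opposcreen_validation_error")
  }
  bad_side <- setdiff(unique(sessions$side), c("left", "right"))
  if (length(bad_side) > 0) {
    abort(paste0("Unknown side label(s): ", paste(bad_side, collapse = ", ")),
          class = "opposcreen_validation_error")
  }
  bad_dir <- sessions$direction < 1L | sessions$direction > g$n_directions
  if (any(bad_dir)) {
    i <- which(bad_dir)[1L]
    abort(sprintf("Direction %d out of 1..%d for hand %s.",
                  sessions$direction[i], g$n_directions, sessions$hand_id[i]),
          class = "opposcreen_validation_error")
  }
  if (any(sessions$t < 0)) {
    i <- which(sessions$t < 0)[1L]
    abort(sprintf("Negative timestamp for hand %s direction %d.",
                  sessions$hand_id[i], sessions$direction[i]),
          class = "opposcreen_validation_error")
  }

  per_trial <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(sessions),
                    .data$hand_id, .data$lap, .data$direction),
    monotone = all(diff(.data$t) > 0),
    mixed_flag = length(unique(.data$collected)) > 1L,
    collected = .data$collected[1L],
    end_t = .data$t[dplyr::n()],
    end_r = sqrt(.data$x[dplyr::n()]^2 + .data$y[dplyr::n()]^2),
    .groups = "drop"
  )
  bad <- !per_trial$monotone
  if (any(bad)) {
    i <- which(bad)[1L]
    abort(sprintf(paste0(
      "Non-monotone timestamps for hand %s lap %d direction %d ",
      "(possible duplicated (lap, direction) trial)."),
      per_trial$hand_id[i], per_trial$lap[i], per_trial$direction[i]),
      class = "opposcreen_validation_error")
  }
  if (any(per_trial$mixed_flag)) {
    i <- which(per_trial$mixed_flag)[1L]
    abort(sprintf("Inconsistent `collected` flag for hand %s direction %d.",
                  per_trial$hand_id[i], per_trial$direction[i]),
          class = "opposcreen_validation_error")
  }
  coll <- per_trial[per_trial$collected, , drop = FALSE]
  if (nrow(coll) > 0) {
    late <- coll$end_t > g$timeout + 1e-9
    if (any(late)) {
      i <- which(late)[1L]
      abort(sprintf("Collected trial exceeds timeout for hand %s direction %d.",
                    coll$hand_id[i], coll$direction[i]),
            class = "opposcreen_validation_error")
    }
    off <- abs(coll$end_r - g$radius) > tol
    if (any(off)) {
      i <- which(off)[1L]
      abort(sprintf(paste0(
        "Final sample of collected trial is %.3f cm from center ",
        "(target radius %.3f) for hand %s direction %d."),
        coll$end_r[i], g$radius, coll$hand_id[i], coll$direction[i]),
        class = "opposcreen_validation_error")
    }
  }
  invisible(sessions)
}

#' Read and write session trajectory files
#'
#' Sessions are stored as a flat UTF-8 CSV with a header and one row per
#' sample, columns `hand_id, group, side, severity, lap, direction,
#' collected, t, x, y`. Numeric fields round-trip at full precision, so
#' `read_sessions(write_sessions(s, f))` reproduces `s` exactly.
#'
#' @param path File path.
#' @param geometry The [task_geometry()] to validate against.
#' @param sessions A `cts_sessions` tibble.
#' @return `read_sessions()`: a validated `cts_sessions` tibble.
#'   `write_sessions()`: `path`, invisibly.
#' @export
read_sessions <- function(path, geometry = task_geometry()) {
  if (!file.exists(path)) {
    abort(sprintf("Session file not found: %s", path),
          class = "opposcreen_io_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  progress = FALSE))
  missing_cols <- setdiff(session_columns, header)
  if (length(missing_cols) > 0) {
    abort(paste0("Session file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "opposcreen_format_error")
  }
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      hand_id = "c", group = "c", side = "c", severity = "i", lap = "i",
      direction = "i", collected = "l", t = "d", x = "d", y = "d"),
    progress = FALSE)
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    abort(paste0("Malformed rows in session file (line ",
                 paste(unique(probs$row), collapse = ", "), ")."),
          class = "opposcreen_format_error")
  }
  as_sessions(data, geometry = geometry)
}

#' @rdname read_sessions
#' @export
write_sessions <- function(sessions, path) {
  if (nrow(sessions) > 0) validate_sessions(sessions)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(sprintf("Directory does not exist: %s", dir),
          class = "opposcreen_io_error")
  }
  readr::write_csv(tibble::as_tibble(sessions)[session_columns], path,
                   progress = FALSE)
  invisible(path)
}

#' Per-hand metadata of a sessions table
#'
#' @param sessions A `cts_sessions` tibble.
#' @return A tibble with one row per hand: `hand_id`, `group`, `side`,
#'   `severity`.
#' @export
session_meta <- function(sessions) {
  dplyr::distinct(tibble::as_tibble(sessions),
                  .data$hand_id, .data$group, .data$side, .data$severity)
}
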