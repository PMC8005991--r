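#' Normalized distance-to-center intensity
#'
#' Maps a thumb position to the grayscale intensity used in the feature
#' image: Euclidean distance from the screen center divided by the target
#' circle radius, clipped at 1. Zero at the center, 1 on or beyond the
#' circle, monotone in distance in between.
#'
#' @param x,y Position in cm (origin at the circle center). Vectorised.
#' @param geometry A [task_geometry()].
#' @return Intensity value(s) in `[0, 1]`.
#' @examples
#' normalize_distance(0.6, 0.8) # 1 cm from center on a 2-cm circle -> 0.5
#' @export
normalize_distance <- function(x, y, geometry = task_geometry()) {
  pmin(sqrt(x^2 + y^2) / geometry$radius, 1.0)
}

# Frame index (1-based) at which a reach completed at time `ct` registers
# on the fixed grid; clamped to the last frame.
reach_frame <- function(ct, geometry) {
  min(geometry$frames_per_trial,
      as.integer(floor(ct * geometry$sample_rate + 1e-9)) + 1L)
}

#' Encode one hand's lap as a grayscale feature image
#'
#' Builds the fixed-size feature image for a hand: one row per direction,
#' one column per frame of the sampling grid (12 x 50 at the default
#' geometry). Each row is the trial's normalized distance-to-center signal
#' linearly interpolated onto the grid. For a collected trial the frame at
#' which the thumb reached the circle is set to 1.0 and all later frames to
#' 0.0 (black fill); values before the reach are clipped to `[0, 1]`. A
#' timed-out trial fills all frames with its observed normalized distances
#' and contains no forced 1.0. A direction with no trial in the lap yields
#' a zero row and is listed in the `flagged_directions` attribute.
#'
#' @param sessions A `cts_sessions` tibble.
#' @param hand A `hand_id` present in `sessions`.
#' @param lap Lap to encode (the second lap is the analysis default).
#' @param geometry A [task_geometry()]; defaults to the one attached to
#'   `sessions`.
#' @return A `feature_image`: an `n_directions` x `frames_per_trial` numeric
#'   matrix in `[0, 1]` with attributes `geometry`, `hand_id`, and
#'   `flagged_directions`.
#' @export
encode_image <- function(sessions, hand, lap = 2L,
                         geometry = sessions_geometry(sessions)) {
  rows <- tibble::as_tibble(sessions)[sessions$hand_id == hand, ]
  if (nrow(rows) == 0) {
    abort(sprintf("No data for hand %s.", hand),
          class = "opposcreen_validation_error")
  }
  rows <- rows[rows$lap == lap, ]
  if (nrow(rows) == 0) {
    abort(sprintf("Hand %s has no trials in lap %d.", hand, lap),
          class = "opposcreen_missing_lap_error")
  }
  nd <- geometry$n_directions
  nf <- geometry$frames_per_trial
  grid <- frame_times(geometry)
  img <- matrix(0, nrow = nd, ncol = nf)
  flagged <- integer(0)
  for (d in seq_len(nd)) {
    tr <- rows[rows$direction == d, ]
    if (nrow(tr) == 0) {
      flagged <- c(flagged, d)
      next
    }
    dist <- normalize_distance(tr$x, tr$y, geometry)
    if (nrow(tr) == 1L) {
      row <- rep(dist, nf)
    } else {
      row <- approx(tr$t, dist, xout = grid, rule = 2)$y
    }
    row <- pmin(pmax(row, 0), 1)
    if (tr$collected[1L]) {
      f <- reach_frame(tr$t[nrow(tr)], geometry)
      row[f] <- 1.0
      if (f < nf) row[(f + 1L):nf] <- 0.0
    }
    img[d, ] <- row
  }
  structure(img, class = c("feature_image", "matrix", "array"),
            geometry = geometry, hand_id = hand,
            flagged_directions = flagged)
}

#' Flatten a feature image to a model input vector
#'
#' Row-major concatenation: direction 1's 50 frames first, then direction
#' 2's, and so on, giving the 600-dimensional input of the full model.
#'
#' @param image A `feature_image` from [encode_image()].
#' @return A bare numeric vector of length `n_directions * frames_per_trial`.
#' @export
flatten <- function(image) {
  as.vector(t(unclass(image)))
}

#' Slice a window of consecutive directions from a feature image
#'
#' Extracts `width` consecutive direction rows starting at `start`, wrapping
#' past direction 12 back to 1 (so start 12, width 4 gives directions
#' 12, 1, 2, 3), and flattens them row-major. These windows feed the
#' per-direction sub-models of the window sweep.
#'
#' @param image A `feature_image`.
#' @param start First direction of the window (1-based).
#' @param width Number of consecutive directions.
#' @return A numeric vector of length `width * frames_per_trial`.
#' @export
slice_window <- function(image, start, width = 4L) {
  g <- attr(image, "geometry", exact = TRUE)
  nd <- if (is.null(g)) nrow(image) else g$n_directions
  if (length(start) != 1L || start != round(start) || start < 1L || start > nd) {
    abort(sprintf("`start` must be an integer in 1..%d.", nd),
          class = "opposcreen_domain_error")
  }
  if (width > nd) {
    abort("`width` must not exceed the number of directions.",
          class = "opposcreen_domain_error")
  }
  rows <- ((start - 1L) + seq_len(width) - 1L) %% nd + 1L
  as.vector(t(unclass(image)[rows, , drop = FALSE]))
}

#' Label of a direction window, matching the sweep tables
#'
#' @param start First direction.
#' @param width Window width.
#' @param n_directions Directions on the circle.
#' @return A label like `"8-11"` or, with wraparound, `"12-3"`.
#' @export
window_label <- function(start, width = 4L, n_directions = 12L) {
  end <- (start - 1L + width - 1L) %% n_directions + 1L
  paste0(start, "-", end)
}

#' Encode every hand of a cohort into feature vectors
#'
#' @inheritParams encode_image
#' @param window Optional window start direction; when given, rows are
#'   `width * frames_per_trial` window slices instead of full images.
#' @param width Window width when `window` is used.
#' @return A numeric matrix with one row per hand (rownames = `hand_id`),
#'   with attributes `meta` (the [session_meta()] tibble) and
#'   `flagged_hands` (hands with at least one missing direction, which are
#'   excluded from training but still scored).
#' @export
encode_cohort <- function(sessions, lap = 2L,
                          geometry = sessions_geometry(sessions),
                          window = NULL, width = 4L) {
  meta <- session_meta(sessions)
  nf <- geometry$frames_per_trial
  p <- if (is.null(window)) geometry$n_directions * nf else width * nf
  X <- matrix(NA_real_, nrow = nrow(meta), ncol = p,
              dimnames = list(meta$hand_id, NULL))
  flagged <- character(0)
  for (i in seq_len(nrow(meta))) {
    img <- encode_image(sessions, meta$hand_id[i], lap = lap,
                        geometry = geometry)
    if (length(attr(img, "flagged_directions")) > 0) {
      flagged <- c(flagged, meta$hand_id[i])
    }
    X[i, ] <- if (is.null(window)) flatten(img) else
      slice_window(img, window, width)
  }
  attr(X, "meta") <- meta
  attr(X, "flagged_hands") <- flagged
  X
}
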