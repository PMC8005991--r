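#' Task geometry of the thumb-reaching game
#'
#' Describes the reaching task: targets appear one at a time on a circle
#' around the screen center, the player slides the thumb from the center to
#' the target, and a reach that takes longer than `timeout` seconds fails.
#' The defaults (2-cm circle, 12 directions, 5-s timeout, 10-Hz sampling)
#' give the canonical 12-row by 50-frame feature image.
#'
#' @param radius Target circle radius in cm.
#' @param n_directions Number of equally spaced target directions.
#' @param timeout Maximum trial duration in seconds.
#' @param sample_rate Position sampling rate in Hz.
#'
#' @return A `task_geometry` object: a list with the four fields above plus
#'   `frames_per_trial = round(timeout * sample_rate)`.
#' @examples
#' g <- task_geometry()
#' g$frames_per_trial # 50
#' @export
task_geometry <- function(radius = 2.0, n_directions = 12L, timeout = 5.0,
                          sample_rate = 10) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    abort("`radius` must be a single positive number.",
          class = "opposcreen_domain_error")
  }
  n_directions <- as.integer(n_directions)
  if (is.na(n_directions) || n_directions < 1L) {
    abort("`n_directions` must be a positive integer.",
          class = "opposcreen_domain_error")
  }
  if (!is.numeric(timeout) || timeout <= 0) {
    abort("`timeout` must be positive.", class = "opposcreen_domain_error")
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    abort("`sample_rate` must be positive.", class = "opposcreen_domain_error")
  }
  structure(
    list(radius = radius, n_directions = n_directions, timeout = timeout,
         sample_rate = sample_rate,
         frames_per_trial = as.integer(round(timeout * sample_rate))),
    class = "task_geometry"
  )
}

#' @export
print.task_geometry <- function(x, ...) {
  cat(sprintf(
    "<task_geometry> %d directions on a %.3g-cm circle, %.3g-s timeout, %.3g Hz (%d frames/trial)\n",
    x$n_directions, x$radius, x$timeout, x$sample_rate, x$frames_per_trial))
  invisible(x)
}

# Times (s since trial start) of the fixed resampling grid.
frame_times <- function(geometry) {
  (seq_len(geometry$frames_per_trial) - 1L) / geometry$sample_rate
}

#' Angle of a numbered target direction
#'
#' Directions are numbered 1 to `n_directions` in a clock-face layout for the
#' right hand: direction `n_directions` (12 by default) points straight up and
#' numbers increase clockwise. For the left hand the layout is mirrored about
#' the vertical axis, matching how the app flips the display between hands.
#' The clock-face assignment is a documented convention; any bijection onto
#' the evenly spaced angles would serve.
#'
#' @param direction Integer direction number(s) in `1:n_directions`.
#' @param side `"right"` or `"left"`.
#' @param n_directions Number of directions on the circle.
#'
#' @return Angle(s) in radians in `[0, 2*pi)`, measured counterclockwise from
#'   the positive x axis.
#' @examples
#' direction_angle(12, "right") # pi/2: straight up
#' direction_angle(3, "right")  # 0: to the right
#' @export
direction_angle <- function(direction, side = c("right", "left"),
                            n_directions = 12L) {
  side <- match.arg(side)
  if (any(direction != round(direction)) ||
      any(direction < 1L) || any(direction > n_directions)) {
    abort(sprintf("`direction` must be an integer in 1..%d.", n_directions),
          class = "opposcreen_domain_error")
  }
  ang <- pi / 2 - direction * 2 * pi / n_directions
  if (side == "left") ang <- pi - ang
  ang %% (2 * pi)
}

#' Target coordinates for a direction
#'
#' @inheritParams direction_angle
#' @param geometry A [task_geometry()].
#' @return A two-column matrix of `x`, `y` target positions in cm.
#' @export
direction_target <- function(direction, side = c("right", "left"),
                             geometry = task_geometry()) {
  side <- match.arg(side)
  a <- direction_angle(direction, side, geometry$n_directions)
  cbind(x = geometry$radius * cos(a), y = geometry$radius * sin(a))
}
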