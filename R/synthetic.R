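#' Motor profile of a simulated hand population
#'
#' Parameters of the synthetic reaching model. Each reach follows a
#' minimum-jerk trajectory — the standard smooth bell-shaped speed curve of
#' human point-to-point movements, whose peak speed is 1.875 times its mean
#' — from the screen center to the target. Impairment is modelled as a
#' global slowing (`speed_scale < 1`) plus an extra movement-time factor in
#' the opposition-like directions (`opposition_penalty > 1` over
#' `penalty_directions`), which reproduces the clinical pattern: patients
#' are slower in every direction and disproportionately slow where the
#' reach requires thumb opposition. Hands and trials carry multiplicative
#' log-normal speed variability, positions carry isotropic Gaussian tremor
#' noise, and a small fraction of reaches stall short of the target and
#' time out.
#'
#' @param base_speed Population mean peak speed in cm/s.
#' @param speed_scale Global slowing factor in (0, 1]; 1 = healthy.
#' @param opposition_penalty Movement-time multiplier in the penalty
#'   directions; 1 = no penalty.
#' @param penalty_directions Directions the penalty applies to. The default
#'   spans both the slow directions (6-9) and the discriminative
#'   thumb-opposition window (8-11).
#' @param tremor_sd Positional noise standard deviation in cm.
#' @param timeout_prob Probability that a reach stalls and times out.
#' @param reaction_time Seconds before movement onset.
#' @param speed_cv_hand,speed_cv_trial Log-scale standard deviations of the
#'   per-hand and per-trial movement-time multipliers.
#' @return A `motor_profile` object.
#' @export
motor_profile <- function(base_speed = 7.5, speed_scale = 1.0,
                          opposition_penalty = 1.0,
                          penalty_directions = 6:11,
                          tremor_sd = 0.05, timeout_prob = 0.01,
                          reaction_time = 0.2,
                          speed_cv_hand = 0.1, speed_cv_trial = 0.05) {
  stopifnot(base_speed > 0, speed_scale > 0, speed_scale <= 1,
            opposition_penalty >= 1, tremor_sd >= 0,
            timeout_prob >= 0, timeout_prob <= 1, reaction_time >= 0,
            speed_cv_hand >= 0, speed_cv_trial >= 0)
  structure(list(base_speed = base_speed, speed_scale = speed_scale,
                 opposition_penalty = opposition_penalty,
                 penalty_directions = as.integer(penalty_directions),
                 tremor_sd = tremor_sd, timeout_prob = timeout_prob,
                 reaction_time = reaction_time,
                 speed_cv_hand = speed_cv_hand,
                 speed_cv_trial = speed_cv_trial),
            class = "motor_profile")
}

#' @rdname motor_profile
#' @details `healthy_profile()` and `cts_profile()` are the default study
#'   conditions: healthy hands at full speed, impaired hands globally
#'   slowed to 60% with a 1.5x movement-time penalty in the opposition
#'   directions and a higher timeout rate.
#' @param ... Overrides passed on to `motor_profile()`.
#' @export
healthy_profile <- function(...) motor_profile(...)

#' @rdname motor_profile
#' @export
cts_profile <- function(speed_scale = 0.6, opposition_penalty = 1.5,
                        timeout_prob = 0.08, ...) {
  motor_profile(speed_scale = speed_scale,
                opposition_penalty = opposition_penalty,
                timeout_prob = timeout_prob, ...)
}

# Minimum-jerk position fraction s(tau) along the path, tau in [0, 1].
min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# Deterministic movement time (s) of a reach before hand/trial variability:
# path length / mean speed, with mean = peak / 1.875 and the opposition
# penalty applied as a time multiplier.
movement_time <- function(profile, direction, geometry) {
  mean_speed <- profile$base_speed * profile$speed_scale / 1.875
  mt <- geometry$radius / mean_speed
  if (direction %in% profile$penalty_directions) {
    mt <- mt * profile$opposition_penalty
  }
  mt
}

#' Simulate one outward reaching trial
#'
#' Draws a single center-to-target reach under a [motor_profile()], using
#' the current RNG state (seed it with [withr::with_seed()] or via
#' [simulate_cohort()]). Successful reaches end with a final sample exactly
#' on the target circle at the collection time; stalled reaches move toward
#' a point short of the circle and hover there until the timeout.
#'
#' @param profile A `motor_profile`.
#' @param direction Target direction 1..12.
#' @param geometry A [task_geometry()].
#' @param side Hand side (controls the direction-to-angle mirroring).
#' @param hand_factor Per-hand movement-time multiplier (drawn once per
#'   hand by the session simulator).
#' @return A list: `samples` tibble (`t`, `x`, `y`), `collected`,
#'   `collect_time` (`NA` when timed out).
#' @export
simulate_trial <- function(profile, direction, geometry = task_geometry(),
                           side = "right", hand_factor = 1.0) {
  tgt <- direction_target(direction, side, geometry)
  u <- unname(c(tgt[1, "x"], tgt[1, "y"])) / geometry$radius
  trial_factor <- rlnorm(1, 0, profile$speed_cv_trial)
  mt <- movement_time(profile, direction, geometry) * hand_factor *
    trial_factor
  onset <- profile$reaction_time
  stalled <- runif(1) < profile$timeout_prob
  ct <- onset + mt
  if (!stalled && ct < geometry$timeout) {
    # keep at least half a frame before the collection touch so the final
    # segment cannot degenerate into a near-zero time step
    tt <- seq(0, ct - 1e-9, by = 1 / geometry$sample_rate)
    tt <- tt[tt < ct - 0.5 / geometry$sample_rate | tt == 0]
    frac <- ifelse(tt <= onset, 0, min_jerk(pmin((tt - onset) / mt, 1)))
    xs <- frac * geometry$radius * u[1] + rnorm(length(tt), 0, profile$tremor_sd)
    ys <- frac * geometry$radius * u[2] + rnorm(length(tt), 0, profile$tremor_sd)
    # the collection event itself is the touch on the target
    tt <- c(tt, ct)
    xs <- c(xs, geometry$radius * u[1])
    ys <- c(ys, geometry$radius * u[2])
    list(samples = tibble::tibble(t = tt, x = xs, y = ys),
         collected = TRUE, collect_time = ct)
  } else {
    # stall short of the circle (or run out the clock mid-reach)
    reach_frac <- if (stalled) runif(1, 0.5, 0.9) else 1.0
    tt <- seq(0, geometry$timeout - 1e-9, by = 1 / geometry$sample_rate)
    frac <- ifelse(tt <= onset, 0,
                   reach_frac * min_jerk(pmin((tt - onset) / mt, 1)))
    xs <- frac * geometry$radius * u[1] + rnorm(length(tt), 0, profile$tremor_sd)
    ys <- frac * geometry$radius * u[2] + rnorm(length(tt), 0, profile$tremor_sd)
    list(samples = tibble::tibble(t = tt, x = xs, y = ys),
         collected = FALSE, collect_time = NA_real_)
  }
}

simulate_session_rows <- function(hand_id, group, side, profile, geometry) {
  hand_factor <- rlnorm(1, 0, profile$speed_cv_hand)
  lap_v <- integer(0); dir_v <- integer(0); coll_v <- logical(0)
  t_v <- numeric(0); x_v <- numeric(0); y_v <- numeric(0)
  for (lap in 1:2) {
    for (d in sample.int(geometry$n_directions)) {  # random presentation order
      tr <- simulate_trial(profile, d, geometry, side, hand_factor)
      n <- nrow(tr$samples)
      lap_v <- c(lap_v, rep.int(lap, n))
      dir_v <- c(dir_v, rep.int(d, n))
      coll_v <- c(coll_v, rep.int(tr$collected, n))
      t_v <- c(t_v, tr$samples$t)
      x_v <- c(x_v, tr$samples$x)
      y_v <- c(y_v, tr$samples$y)
    }
  }
  tibble::tibble(hand_id = hand_id, group = group, side = side,
                 severity = NA_integer_, lap = lap_v, direction = dir_v,
                 collected = coll_v, t = t_v, x = x_v, y = y_v)
}

#' Simulate a case-control cohort of reaching sessions
#'
#' Generates `n_healthy + n_cts` hands, each playing two measurement laps
#' of all 12 directions in random order, fully reproducible from `seed`.
#'
#' @param n_healthy,n_cts Hand counts per group (the reference clinical
#'   cohort had 27 healthy and 36 CTS hands).
#' @param healthy_profile,cts_profile Group [motor_profile()]s.
#' @param geometry A [task_geometry()].
#' @param seed Integer seed fixing the whole cohort.
#' @return A validated `cts_sessions` tibble.
#' @examples
#' s <- simulate_cohort(n_healthy = 2, n_cts = 2, seed = 7)
#' session_meta(s)
#' @export
simulate_cohort <- function(n_healthy = 27L, n_cts = 36L,
                            healthy_profile = opposcreen::healthy_profile(),
                            cts_profile = opposcreen::cts_profile(),
                            geometry = task_geometry(), seed = 1L) {
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (i in seq_len(n_healthy)) {
      side <- if (i %% 2 == 0) "left" else "right"
      rows[[length(rows) + 1L]] <- simulate_session_rows(
        sprintf("H%03d", i), "healthy", side, healthy_profile, geometry)
    }
    for (i in seq_len(n_cts)) {
      side <- if (i %% 2 == 0) "left" else "right"
      rows[[length(rows) + 1L]] <- simulate_session_rows(
        sprintf("C%03d", i), "cts", side, cts_profile, geometry)
    }
    as_sessions(dplyr::bind_rows(rows), geometry = geometry)
  })
}
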