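#' Kinematic summary of a single reaching trial
#'
#' Computes the three per-direction movement summaries: time to collect,
#' mean velocity, and maximum velocity. Velocities come from finite
#' differences of consecutive raw samples (Euclidean displacement over
#' elapsed time); no smoothing is applied. A trial that timed out
#' contributes the full timeout as its time but its observed samples still
#' contribute to the velocity summaries.
#'
#' @param t,x,y Numeric vectors of sample times (s) and positions (cm) for
#'   one trial, in time order.
#' @param collected Did the reach succeed before the timeout?
#' @param timeout Trial timeout in seconds, used as the time for failed
#'   reaches.
#' @return A one-row tibble with `time_to_collect`, `mean_velocity`,
#'   `max_velocity`.
#' @examples
#' # 2-cm straight reach at constant speed, collected at 1 s
#' trial_kinematics(t = seq(0, 1, 0.25), x = seq(0, 2, 0.5), y = rep(0, 5))
#' @export
trial_kinematics <- function(t, x, y, collected = TRUE, timeout = 5.0) {
  if (length(t) < 2L) {
    abort("A trial needs at least 2 samples to compute velocities.",
          class = "opposcreen_insufficient_data")
  }
  dt <- diff(t)
  v <- sqrt(diff(x)^2 + diff(y)^2) / dt
  tibble::tibble(
    time_to_collect = if (isTRUE(collected)) t[length(t)] else timeout,
    mean_velocity = mean(v),
    max_velocity = max(v)
  )
}

#' Per-hand, per-direction kinematics for a cohort
#'
#' Applies [trial_kinematics()] to every trial of the requested lap and
#' returns one row per (hand, direction). Directions with no trial in that
#' lap are kept as rows with `missing = TRUE` and `NA` summaries rather than
#' silently dropped; hands with no data at all in the lap trigger a warning
#' and are recorded in the `missing_lap_hands` attribute of the result.
#'
#' @param sessions A `cts_sessions` tibble.
#' @param lap Which measurement lap to summarise (the second lap is the
#'   analysis default; the first is played as practice).
#' @return A tibble with columns `hand_id`, `group`, `side`, `direction`,
#'   `collected`, `missing`, `time_to_collect`, `mean_velocity`,
#'   `max_velocity`.
#' @export
cohort_kinematics <- function(sessions, lap = 2L) {
  g <- sessions_geometry(sessions)
  meta <- session_meta(sessions)
  sub <- tibble::as_tibble(sessions)[sessions$lap == lap, ]

  absent <- setdiff(meta$hand_id, unique(sub$hand_id))
  if (length(absent) > 0) {
    warn(paste0("No lap-", lap, " data for hand(s): ",
                paste(absent, collapse = ", ")))
  }

  per_trial <- if (nrow(sub) == 0) {
    tibble::tibble(hand_id = character(0), direction = integer(0),
                   collected = logical(0), n_samples = integer(0),
                   time_to_collect = numeric(0),
                   mean_velocity = numeric(0), max_velocity = numeric(0))
  } else dplyr::summarise(
    dplyr::group_by(sub, .data$hand_id, .data$direction),
    collected = .data$collected[1L],
    n_samples = dplyr::n(),
    time_to_collect = if (.data$collected[1L]) .data$t[dplyr::n()] else g$timeout,
    mean_velocity = if (dplyr::n() >= 2L)
      mean(sqrt(diff(.data$x)^2 + diff(.data$y)^2) / diff(.data$t)) else NA_real_,
    max_velocity = if (dplyr::n() >= 2L)
      max(sqrt(diff(.data$x)^2 + diff(.data$y)^2) / diff(.data$t)) else NA_real_,
    .groups = "drop"
  )

  grid <- tidyr::expand_grid(hand_id = meta$hand_id,
                             direction = seq_len(g$n_directions))
  out <- dplyr::left_join(grid, per_trial, by = c("hand_id", "direction"))
  out$missing <- is.na(out$n_samples)
  out$n_samples <- NULL
  out <- dplyr::left_join(out, meta[c("hand_id", "group", "side")],
                          by = "hand_id")
  out <- out[c("hand_id", "group", "side", "direction", "collected",
               "missing", "time_to_collect", "mean_velocity", "max_velocity")]
  attr(out, "missing_lap_hands") <- absent
  out
}

#' Group comparison of per-direction kinematics
#'
#' Two-sample two-tailed t tests per (direction, metric), comparing the two
#' group labels present in the table. Student's pooled-variance test is the
#' default (`var_equal = TRUE`); Welch's variant is available. The t
#' statistic is signed as `mean_a - mean_b`, with group a = `"healthy"` when
#' present (alphabetically first label otherwise).
#'
#' @param kin A cohort kinematics table from [cohort_kinematics()].
#' @param metrics Metric columns to test.
#' @param var_equal Use the pooled-variance (Student) test.
#' @return A tibble with one row per (direction, metric): group labels and
#'   means, `t_statistic`, and two-tailed `p_value`.
#' @export
compare_groups <- function(kin,
                           metrics = c("time_to_collect", "mean_velocity",
                                       "max_velocity"),
                           var_equal = TRUE) {
  groups <- sort(unique(kin$group))
  if (length(groups) != 2L) {
    abort("`kin` must contain exactly two group labels.",
          class = "opposcreen_validation_error")
  }
  if ("healthy" %in% groups) groups <- c("healthy", setdiff(groups, "healthy"))

  rows <- list()
  for (d in sort(unique(kin$direction))) {
    for (m in metrics) {
      va <- kin[[m]][kin$direction == d & kin$group == groups[1L]]
      vb <- kin[[m]][kin$direction == d & kin$group == groups[2L]]
      va <- va[!is.na(va)]
      vb <- vb[!is.na(vb)]
      if (length(va) < 2L || length(vb) < 2L) {
        abort(sprintf(
          "Fewer than 2 hands with data in a group (direction %d, %s).", d, m),
          class = "opposcreen_degenerate_error")
      }
      tt <- tryCatch(
        t.test(va, vb, var.equal = var_equal),
        error = function(e) {
          # both samples constant: t.test refuses; the limit is exact
          d0 <- mean(va) - mean(vb)
          list(statistic = if (d0 == 0) 0 else sign(d0) * Inf,
               p.value = if (d0 == 0) 1 else 0)
        })
      rows[[length(rows) + 1L]] <- tibble::tibble(
        direction = d, metric = m,
        group_a = groups[1L], group_b = groups[2L],
        mean_a = mean(va), mean_b = mean(vb),
        t_statistic = unname(tt$statistic), p_value = unname(tt$p.value))
    }
  }
  dplyr::bind_rows(rows)
}

#' Chi-square test on a 2 x 2 count table
#'
#' Convenience wrapper for comparing categorical metadata (sex, hand side)
#' between groups, as used alongside the kinematic t tests.
#'
#' @param counts A 2 x 2 matrix of counts (groups in rows).
#' @param correct Apply Yates' continuity correction.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
compare_counts <- function(counts, correct = FALSE) {
  if (!is.matrix(counts) || any(dim(counts) != c(2L, 2L))) {
    abort("`counts` must be a 2 x 2 matrix.",
          class = "opposcreen_validation_error")
  }
  ct <- chisq.test(counts, correct = correct)
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}
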