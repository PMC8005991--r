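# Deterministic hand-built session: straight-line reaches at constant speed
# along each direction ray, final sample exactly on the circle.
line_session <- function(hand_id = "H001", group = "healthy", side = "right",
                         laps = 1:2, directions = 1:12, duration = 1.0,
                         n_samples = 6L, geometry = task_geometry()) {
  rows <- list()
  for (lap in laps) {
    for (d in directions) {
      tgt <- direction_target(d, side, geometry)
      tt <- seq(0, duration, length.out = n_samples)
      frac <- tt / duration
      rows[[length(rows) + 1L]] <- tibble::tibble(
        hand_id = hand_id, group = group, side = side,
        severity = NA_integer_, lap = as.integer(lap),
        direction = as.integer(d), collected = TRUE,
        t = tt, x = frac * tgt[1, "x"], y = frac * tgt[1, "y"])
    }
  }
  as_sessions(dplyr::bind_rows(rows), geometry = geometry)
}

# Memoised cohorts so expensive simulations are shared across test files.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(key, fun) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- fun()
  .cohort_cache[[key]]
}

default_cohort_63 <- function() {
  cached_cohort("default63", function() simulate_cohort(27, 36, seed = 7))
}

small_cohort <- function() {
  cached_cohort("small", function() simulate_cohort(14, 6, seed = 3))
}

# Independent pair-counting AUC oracle: concordant pairs + half ties,
# enumerated explicitly.
auc_pair_counting <- function(scores, labels, positive = "cts") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Independent Youden oracle: exhaustive search over candidate cutoffs.
youden_brute_force <- function(scores, labels, positive = "cts") {
  cand <- c(-Inf, sort(unique(scores)), Inf)
  best <- -Inf
  for (cut in cand) {
    sens <- mean(scores[labels == positive] >= cut)
    spec <- mean(scores[labels != positive] < cut)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Textbook pooled-variance two-sample t statistic.
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}
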