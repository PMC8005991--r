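#' ROC curve of anomaly scores
#'
#' Sweeps the decision cutoff over every distinct score (plus sentinels at
#' minus and plus infinity) with the rule "predict CTS when the
#' reconstruction error is at least the cutoff". Sensitivity is the fraction
#' of CTS hands at or above the cutoff, specificity the fraction of healthy
#' hands below it. The area under the curve is computed by the trapezoidal
#' rule, which on this threshold set equals the Mann-Whitney pair-counting
#' probability (concordant pairs plus half the ties).
#'
#' @param scores Numeric anomaly scores (higher = more anomalous).
#' @param labels Group labels, one per score.
#' @param positive The label treated as the positive (disease) class.
#' @return A `cts_roc` object: a `points` tibble of
#'   (`threshold`, `sensitivity`, `specificity`) and the `auc`.
#' @export
roc_curve <- function(scores, labels, positive = "cts") {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have the same length.",
          class = "opposcreen_evaluation_error")
  }
  if (!all(is.finite(scores))) {
    abort("All scores must be finite.", class = "opposcreen_evaluation_error")
  }
  pos <- labels == positive
  if (!any(pos) || all(pos)) {
    abort("Both classes must be present to build a ROC curve.",
          class = "opposcreen_evaluation_error")
  }
  th <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(th, function(cut) mean(scores[pos] >= cut), numeric(1))
  spec <- vapply(th, function(cut) mean(scores[!pos] < cut), numeric(1))
  pts <- tibble::tibble(threshold = th, sensitivity = sens,
                        specificity = spec)
  fpr <- rev(1 - spec)  # ascending in false-positive rate
  tpr <- rev(sens)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, positive = positive,
                 n_positive = sum(pos), n_negative = sum(!pos)),
            class = "cts_roc")
}

#' @export
print.cts_roc <- function(x, ...) {
  cat(sprintf("<cts_roc> AUC %.3f (%d %s vs %d others, %d thresholds)\n",
              x$auc, x$n_positive, x$positive, x$n_negative,
              nrow(x$points)))
  invisible(x)
}

#' @export
plot.cts_roc <- function(x, ...) {
  plot(1 - x$points$specificity, x$points$sensitivity, type = "s",
       xlab = "1 - specificity", ylab = "Sensitivity",
       main = sprintf("ROC (AUC = %.2f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# Rank-based (Mann-Whitney) AUC; used as an internal cross-check of the
# trapezoidal computation.
auc_rank <- function(scores, labels, positive = "cts") {
  pos <- labels == positive
  r <- rank(scores)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

#' Youden-optimal cutoff of a ROC curve
#'
#' Chooses the cutoff maximising the Youden index
#' (sensitivity + specificity - 1). Ties are broken toward higher
#' specificity: as a screening tool feeding confirmatory diagnosis, the
#' cheaper error at equal Youden index is the false positive.
#'
#' @param roc A `cts_roc` from [roc_curve()].
#' @return A `cutoff_choice`: `threshold`, `sensitivity`, `specificity`,
#'   `youden`.
#' @export
youden_cutoff <- function(roc) {
  pts <- roc$points
  j <- pts$sensitivity + pts$specificity - 1
  cand <- which(j >= max(j) - 1e-12)
  cand <- cand[pts$specificity[cand] >= max(pts$specificity[cand]) - 1e-12]
  best <- cand[which.max(pts$threshold[cand])]
  structure(list(threshold = pts$threshold[best],
                 sensitivity = pts$sensitivity[best],
                 specificity = pts$specificity[best],
                 youden = j[best]),
            class = "cutoff_choice")
}

#' @export
print.cutoff_choice <- function(x, ...) {
  cat(sprintf(
    "<cutoff_choice> threshold %.4g: sensitivity %d%%, specificity %d%%, Youden %.3f\n",
    x$threshold, round(100 * x$sensitivity), round(100 * x$specificity),
    x$youden))
  invisible(x)
}

#' Confusion matrix at a cutoff
#'
#' Classifies each hand by comparing its score to the cutoff (scores at or
#' above the cutoff are predicted CTS) and tabulates against the true
#' labels.
#'
#' @inheritParams roc_curve
#' @param threshold Decision cutoff on the score.
#' @return A `confusion_matrix` with counts `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_at <- function(scores, labels, threshold, positive = "cts") {
  pos <- labels == positive
  pred <- scores >= threshold
  confusion_matrix(tp = sum(pos & pred), fn = sum(pos & !pred),
                   tn = sum(!pos & !pred), fp = sum(!pos & pred))
}

#' @rdname confusion_at
#' @param tp,fn,tn,fp Non-negative counts (positive class = CTS).
#' @export
confusion_matrix <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Confusion counts must be non-negative integers.",
          class = "opposcreen_validation_error")
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' Sensitivity and specificity of a confusion matrix
#'
#' @param x A `confusion_matrix`.
#' @param percent Return the value as an integer-rounded percentage
#'   (the convention of clinical screening tables) instead of a proportion.
#' @return Sensitivity `tp / (tp + fn)` or specificity `tn / (tn + fp)`.
#' @export
sensitivity <- function(x, percent = FALSE) {
  v <- x$tp / (x$tp + x$fn)
  if (percent) round(100 * v) else v
}

#' @rdname sensitivity
#' @export
specificity <- function(x, percent = FALSE) {
  v <- x$tn / (x$tn + x$fp)
  if (percent) round(100 * v) else v
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp %d, fn %d, tn %d, fp %d\n",
              x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("  sensitivity %d%%, specificity %d%%\n",
              sensitivity(x, percent = TRUE),
              specificity(x, percent = TRUE)))
  invisible(x)
}

#' Sweep 4-direction sub-models over all start directions
#'
#' For each start direction, slices every hand's feature image to the
#' window of `width` consecutive directions (wrapping past 12), retrains an
#' autoencoder of matching input size on the same healthy training hands,
#' scores the validation hands, and reports the AUC plus the
#' sensitivity/specificity at that window's own Youden-optimal cutoff. The
#' result is a 12-row table showing which directional movements carry the
#' screening signal; in clinical data the thumb-opposition window (8-11)
#' dominates.
#'
#' @param sessions A `cts_sessions` tibble containing healthy and CTS hands.
#' @param width Window width in directions.
#' @param lap Lap to encode.
#' @param n_train Healthy hands used for training (ignored when
#'   `train_ids` is given).
#' @param hidden_dim,epochs,learning_rate Autoencoder hyperparameters.
#' @param seed Seed for the training split and weight initialisation.
#' @param train_ids Optional explicit training hand ids (shared across
#'   windows by construction either way).
#' @return A tibble with one row per window: `window`, `start`,
#'   `sensitivity_pct`, `specificity_pct`, `auc`.
#' @export
window_sweep <- function(sessions, width = 4L, lap = 2L, n_train = 12L,
                         hidden_dim = 10L, epochs = 500L,
                         learning_rate = 0.01, seed = 1L,
                         train_ids = NULL) {
  geometry <- sessions_geometry(sessions)
  meta <- session_meta(sessions)
  images <- lapply(meta$hand_id, encode_image, sessions = sessions,
                   lap = lap, geometry = geometry)
  names(images) <- meta$hand_id
  if (is.null(train_ids)) {
    train_ids <- split_training(meta, n_train, seed)
  }
  nf <- geometry$frames_per_trial

  rows <- lapply(seq_len(geometry$n_directions), function(start) {
    lab <- window_label(start, width, geometry$n_directions)
    tryCatch({
      X <- do.call(rbind, lapply(images, slice_window, start = start,
                                 width = width))
      rownames(X) <- meta$hand_id
      attr(X, "meta") <- meta
      cfg <- ae_config(input_dim = width * nf, hidden_dim = hidden_dim,
                       epochs = epochs, learning_rate = learning_rate,
                       seed = derive_seed(seed, start))
      model <- train_autoencoder(X[train_ids, , drop = FALSE], cfg)
      sc <- score_cohort(model, X)
      roc <- roc_curve(sc$mse, sc$group)
      cut <- youden_cutoff(roc)
      tibble::tibble(window = lab, start = start,
                     sensitivity_pct = round(100 * cut$sensitivity),
                     specificity_pct = round(100 * cut$specificity),
                     auc = roc$auc)
    }, error = function(e) {
      abort(sprintf("Window %s: %s", lab, conditionMessage(e)),
            class = "opposcreen_evaluation_error")
    })
  })
  dplyr::bind_rows(rows)
}
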