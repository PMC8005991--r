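# One user-facing seed fans out to stage seeds so the split, the weights
# and the sweep can be varied independently; kept inside 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Choose the healthy hands used for autoencoder training
#'
#' Draws `n_train` healthy hands at random under `seed`; the remaining
#' healthy hands and all CTS hands form the validation set. Hands flagged
#' during encoding (missing directions) can be excluded via `exclude`.
#'
#' @param meta A [session_meta()] tibble.
#' @param n_train Number of healthy training hands.
#' @param seed Split seed.
#' @param exclude Hand ids ineligible for training.
#' @return Character vector of training hand ids.
#' @export
split_training <- function(meta, n_train = 12L, seed = 1L,
                           exclude = character(0)) {
  healthy <- setdiff(meta$hand_id[meta$group == "healthy"], exclude)
  if (length(healthy) < n_train) {
    abort(sprintf("Need at least %d healthy hands for training; found %d.",
                  n_train, length(healthy)),
          class = "opposcreen_config_error")
  }
  withr::with_seed(as.integer(seed), sample(healthy, n_train))
}

#' Run the full screening pipeline on a cohort
#'
#' Encodes every hand's second lap as a feature image, trains the
#' autoencoder on a random subset of healthy hands, scores the remaining
#' hands by reconstruction error, and evaluates screening performance:
#' ROC curve, AUC, Youden-optimal cutoff, and the confusion matrix at that
#' cutoff. Optionally also runs the 4-direction [window_sweep()] with the
#' same training hands.
#'
#' @param sessions A `cts_sessions` tibble with healthy and CTS hands.
#' @param n_train Healthy hands used for training.
#' @param hidden_dim,epochs,learning_rate Autoencoder hyperparameters.
#' @param lap Lap to analyse.
#' @param seed Master seed; stage seeds (split, weights, sweep) are derived
#'   from it, so the whole run is reproducible from this one integer.
#' @param sweep Also run the window sweep.
#' @param width Window width for the sweep.
#' @return A `cts_screening` list: `scores` tibble, `roc`, `cutoff`,
#'   `confusion`, `auc`, `train_ids`, `sweep` (or `NULL`), and `settings`.
#' @export
run_screening <- function(sessions, n_train = 12L, hidden_dim = 10L,
                          epochs = 500L, learning_rate = 0.01, lap = 2L,
                          seed = 1L, sweep = FALSE, width = 4L) {
  geometry <- sessions_geometry(sessions)
  meta <- session_meta(sessions)
  if (sum(meta$group == "healthy") < n_train) {
    abort(sprintf("Need at least %d healthy hands; cohort has %d.",
                  n_train, sum(meta$group == "healthy")),
          class = "opposcreen_config_error")
  }
  features <- encode_cohort(sessions, lap = lap, geometry = geometry)
  train_ids <- split_training(meta, n_train, derive_seed(seed, 1L),
                              exclude = attr(features, "flagged_hands"))
  cfg <- ae_config(input_dim = ncol(features), hidden_dim = hidden_dim,
                   epochs = epochs, learning_rate = learning_rate,
                   seed = derive_seed(seed, 2L))
  model <- train_autoencoder(features[train_ids, , drop = FALSE], cfg)
  scores <- score_cohort(model, features)
  roc <- roc_curve(scores$mse, scores$group)
  cutoff <- youden_cutoff(roc)
  confusion <- confusion_at(scores$mse, scores$group, cutoff$threshold)
  sweep_tbl <- if (sweep) {
    window_sweep(sessions, width = width, lap = lap,
                 hidden_dim = hidden_dim, epochs = epochs,
                 learning_rate = learning_rate,
                 seed = derive_seed(seed, 3L), train_ids = train_ids)
  }
  structure(list(scores = scores, roc = roc, cutoff = cutoff,
                 confusion = confusion, auc = roc$auc,
                 train_ids = train_ids, model = model, sweep = sweep_tbl,
                 settings = list(n_train = n_train, hidden_dim = hidden_dim,
                                 epochs = epochs,
                                 learning_rate = learning_rate, lap = lap,
                                 seed = seed, width = width)),
            class = "cts_screening")
}

#' @export
print.cts_screening <- function(x, ...) {
  cat(sprintf(
    "<cts_screening> %d validation hands (%d trained): AUC %.3f, sensitivity %d%%, specificity %d%% at Youden cutoff %.4g\n",
    nrow(x$scores), length(x$train_ids), x$auc,
    sensitivity(x$confusion, percent = TRUE),
    specificity(x$confusion, percent = TRUE), x$cutoff$threshold))
  if (!is.null(x$sweep)) {
    cat("  window sweep:\n")
    print(x$sweep)
  }
  invisible(x)
}

#' Write a screening results bundle to a directory
#'
#' Writes `scores.csv`, `roc.csv`, `confusion.csv`, optionally `sweep.csv`,
#' and a `manifest.json` recording the settings, derived seeds, package
#' version and an input-content hash, so any bundle can be reproduced from
#' its manifest.
#'
#' @param result A `cts_screening` from [run_screening()].
#' @param dir Output directory (created if needed).
#' @param sessions The input sessions (hashed into the manifest).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir, sessions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$scores, file.path(dir, "scores.csv"))
  readr::write_csv(result$roc$points, file.path(dir, "roc.csv"))
  cm <- result$confusion
  readr::write_csv(tibble::tibble(
    tp = cm$tp, fn = cm$fn, tn = cm$tn, fp = cm$fp,
    sensitivity_pct = sensitivity(cm, percent = TRUE),
    specificity_pct = specificity(cm, percent = TRUE),
    threshold = result$cutoff$threshold, auc = result$auc),
    file.path(dir, "confusion.csv"))
  if (!is.null(result$sweep)) {
    readr::write_csv(result$sweep, file.path(dir, "sweep.csv"))
  }
  manifest <- list(
    package = "opposcreen",
    version = as.character(utils::packageVersion("opposcreen")),
    settings = result$settings,
    train_ids = result$train_ids,
    input_hash = if (!is.null(sessions)) rlang::hash(sessions) else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
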