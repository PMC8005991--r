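#' Autoencoder configuration
#'
#' Hyperparameters of the screening autoencoder. The architecture is a
#' single nonlinear hidden layer between an input and output of the feature
#' dimension (600 for full images, 200 for 4-direction windows), with a
#' 10-unit bottleneck by default so reconstruction must pass through a
#' compressed code. The output activation is a sigmoid because the inputs
#' are intensities in `[0, 1]`; training minimises mean squared
#' reconstruction error, the same statistic used for screening. Optimisation
#' is full-batch Adam (or seeded mini-batches when `batch_size` is set) with
#' early stopping once the training loss stops improving.
#'
#' @param input_dim Feature dimension.
#' @param hidden_dim Bottleneck width; must be smaller than `input_dim`.
#' @param epochs Maximum training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size, or `NULL` for full batch.
#' @param seed Seed fixing weight initialisation and batch order.
#' @param activation Hidden-layer activation.
#' @param patience Epochs without improvement before early stopping.
#' @param tol Minimum loss decrease that counts as an improvement.
#' @return An `ae_config` object.
#' @export
ae_config <- function(input_dim, hidden_dim = 10L, epochs = 500L,
                      learning_rate = 0.01, batch_size = NULL, seed = 1L,
                      activation = c("sigmoid", "tanh", "relu"),
                      patience = 50L, tol = 1e-8) {
  activation <- match.arg(activation)
  input_dim <- as.integer(input_dim)
  hidden_dim <- as.integer(hidden_dim)
  if (hidden_dim >= input_dim) {
    abort("`hidden_dim` must be smaller than `input_dim` (compression).",
          class = "opposcreen_config_error")
  }
  if (epochs < 1L) {
    abort("`epochs` must be at least 1.", class = "opposcreen_config_error")
  }
  structure(list(input_dim = input_dim, hidden_dim = hidden_dim,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = batch_size, seed = as.integer(seed),
                 activation = activation, patience = as.integer(patience),
                 tol = tol),
            class = "ae_config")
}

act_fun <- function(name) {
  switch(name,
         sigmoid = list(f = plogis, grad = function(a) a * (1 - a)),
         tanh = list(f = tanh, grad = function(a) 1 - a^2),
         relu = list(f = function(z) pmax(z, 0),
                     grad = function(a) (a > 0) * 1))
}

#' Train the screening autoencoder on healthy feature vectors
#'
#' Fits the encoder/decoder weights by backpropagation with Adam,
#' minimising the mean squared error between input and reconstruction.
#' Training data should be healthy hands only: the model then reconstructs
#' healthy movement patterns well and anomalous (impaired) patterns poorly,
#' which is what makes the reconstruction error a screening score. The
#' output biases are initialised to the logit of the training column means
#' and the weights to seeded Glorot-uniform draws, so runs are fully
#' deterministic given `config$seed`. The hands used for training are
#' recorded so that scoring can exclude them from validation.
#'
#' @param x Numeric matrix of training vectors, one hand per row (rownames
#'   are used as hand ids); values in `[0, 1]`.
#' @param config An [ae_config()] with matching `input_dim`.
#' @return An `anomaly_model`: weight matrices, the config, the per-epoch
#'   training loss trace, and `trained_on` (training hand ids).
#' @export
train_autoencoder <- function(x, config) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (!all(is.finite(x))) {
    abort("Training matrix contains non-finite values.",
          class = "opposcreen_config_error")
  }
  if (ncol(x) != config$input_dim) {
    abort(sprintf("Training vectors have %d components; config expects %d.",
                  ncol(x), config$input_dim),
          class = "opposcreen_config_error")
  }
  if (nrow(x) < 2L) {
    abort("At least 2 training vectors are required.",
          class = "opposcreen_config_error")
  }
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("v", seq_len(nrow(x)))

  n <- nrow(x); p <- config$input_dim; h <- config$hidden_dim
  act <- act_fun(config$activation)
  bs <- if (is.null(config$batch_size)) n else min(config$batch_size, n)

  fit <- withr::with_seed(config$seed, {
    s1 <- sqrt(6 / (p + h))
    W1 <- matrix(runif(p * h, -s1, s1), p, h)
    b1 <- rep(0, h)
    W2 <- matrix(runif(h * p, -s1, s1), h, p)
    # start the decoder at the marginal mean so early epochs refine shape,
    # not scale
    b2 <- qlogis(pmin(pmax(colMeans(x), 1e-4), 1 - 1e-4))

    adam <- list(); for (nm in c("W1", "b1", "W2", "b2")) {
      adam[[nm]] <- list(m = 0, v = 0)
    }
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0
    upd <- function(state, g) {
      state$m <- beta1 * state$m + (1 - beta1) * g
      state$v <- beta2 * state$v + (1 - beta2) * g^2
      state
    }

    trace <- numeric(config$epochs)
    best <- Inf; best_w <- NULL; stall <- 0L
    for (e in seq_len(config$epochs)) {
      idx <- if (bs < n) sample.int(n) else seq_len(n)
      batches <- split(idx, ceiling(seq_along(idx) / bs))
      for (b in batches) {
        Xb <- x[b, , drop = FALSE]
        H <- act$f(sweep(Xb %*% W1, 2, b1, "+"))
        Y <- plogis(sweep(H %*% W2, 2, b2, "+"))
        dY <- 2 * (Y - Xb) / (length(b) * p)
        dZ2 <- dY * Y * (1 - Y)
        gW2 <- crossprod(H, dZ2); gb2 <- colSums(dZ2)
        dH <- dZ2 %*% t(W2)
        dZ1 <- dH * act$grad(H)
        gW1 <- crossprod(Xb, dZ1); gb1 <- colSums(dZ1)

        step <- step + 1
        c1 <- 1 - beta1^step; c2 <- 1 - beta2^step
        adam$W1 <- upd(adam$W1, gW1)
        adam$b1 <- upd(adam$b1, gb1)
        adam$W2 <- upd(adam$W2, gW2)
        adam$b2 <- upd(adam$b2, gb2)
        W1 <- W1 - config$learning_rate * (adam$W1$m / c1) /
          (sqrt(adam$W1$v / c2) + eps)
        b1 <- b1 - config$learning_rate * (adam$b1$m / c1) /
          (sqrt(adam$b1$v / c2) + eps)
        W2 <- W2 - config$learning_rate * (adam$W2$m / c1) /
          (sqrt(adam$W2$v / c2) + eps)
        b2 <- b2 - config$learning_rate * (adam$b2$m / c1) /
          (sqrt(adam$b2$v / c2) + eps)
      }
      H <- act$f(sweep(x %*% W1, 2, b1, "+"))
      Y <- plogis(sweep(H %*% W2, 2, b2, "+"))
      loss <- mean((Y - x)^2)
      if (!is.finite(loss)) {
        abort(sprintf("Training diverged (non-finite loss at epoch %d).", e),
              class = "opposcreen_divergence_error")
      }
      trace[e] <- loss
      if (loss < best - config$tol) {
        best <- loss
        best_w <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    c(best_w, list(trace = trace[seq_len(e)], best = best))
  })

  structure(list(W1 = fit$W1, b1 = fit$b1, W2 = fit$W2, b2 = fit$b2,
                 config = config, loss_trace = fit$trace,
                 final_loss = fit$best, trained_on = ids),
            class = "anomaly_model")
}

#' @export
print.anomaly_model <- function(x, ...) {
  cat(sprintf(
    "<anomaly_model> %d-%d-%d autoencoder (%s hidden), trained on %d hands, final MSE %.3g\n",
    x$config$input_dim, x$config$hidden_dim, x$config$input_dim,
    x$config$activation, length(x$trained_on), x$final_loss))
  invisible(x)
}

#' Reconstruct feature vectors through the autoencoder
#'
#' @param model An `anomaly_model`.
#' @param x A feature vector or a matrix of row vectors.
#' @return Reconstruction(s) with the same shape as `x`.
#' @export
reconstruct <- function(model, x) {
  vec <- is.vector(x)
  if (vec) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$config$input_dim) {
    abort(sprintf("Vector length %d does not match model input dimension %d.",
                  ncol(x), model$config$input_dim),
          class = "opposcreen_dimension_error")
  }
  act <- act_fun(model$config$activation)
  H <- act$f(sweep(x %*% model$W1, 2, model$b1, "+"))
  Y <- plogis(sweep(H %*% model$W2, 2, model$b2, "+"))
  if (vec) as.vector(Y) else Y
}

#' Reconstruction error (anomaly score)
#'
#' Mean squared error between a feature vector and its reconstruction —
#' the screening score: small for movement patterns resembling the healthy
#' training data, large for anomalous ones.
#'
#' @inheritParams reconstruct
#' @return A non-negative MSE per input row (scalar for a vector input).
#' @export
reconstruction_error <- function(model, x) {
  vec <- is.vector(x)
  if (vec) x <- matrix(x, nrow = 1L)
  Y <- reconstruct(model, x)
  mse <- rowMeans((x - Y)^2)
  if (!is.null(rownames(x))) names(mse) <- rownames(x)
  if (vec) unname(mse[1L]) else mse
}

#' Score a cohort of encoded hands
#'
#' Computes the reconstruction error of every hand in a feature matrix,
#' excluding the hands the model was trained on (they are not a valid
#' validation set; set `include_training = TRUE` only for diagnostics).
#'
#' @param model An `anomaly_model`.
#' @param features A feature matrix from [encode_cohort()] (rownames =
#'   hand ids, optional `meta` attribute supplying group labels).
#' @param labels Optional named or positional group labels overriding the
#'   `meta` attribute.
#' @param include_training Score training hands too.
#' @return A tibble with `hand_id`, `mse`, `group`.
#' @export
score_cohort <- function(model, features, labels = NULL,
                         include_training = FALSE) {
  ids <- rownames(features)
  if (is.null(ids)) ids <- paste0("v", seq_len(nrow(features)))
  if (is.null(labels)) {
    meta <- attr(features, "meta", exact = TRUE)
    labels <- if (is.null(meta)) rep(NA_character_, length(ids)) else
      meta$group[match(ids, meta$hand_id)]
  }
  keep <- if (include_training) rep(TRUE, length(ids)) else
    !(ids %in% model$trained_on)
  if (!any(keep)) {
    abort("No hands left to score after excluding the training set.",
          class = "opposcreen_evaluation_error")
  }
  mse <- reconstruction_error(model, features[keep, , drop = FALSE])
  tibble::tibble(hand_id = ids[keep], mse = unname(mse),
                 group = labels[keep])
}

#' Save or load an autoencoder in a portable text format
#'
#' Models are serialised as versioned JSON: layer sizes, activation,
#' training hand ids, and row-major weight matrices at full precision.
#'
#' @param model An `anomaly_model`.
#' @param path File path.
#' @return `write_anomaly_model()`: `path`, invisibly.
#'   `read_anomaly_model()`: the restored `anomaly_model`.
#' @export
write_anomaly_model <- function(model, path) {
  payload <- list(
    format = "opposcreen-ae", version = 1L,
    input_dim = model$config$input_dim, hidden_dim = model$config$hidden_dim,
    activation = model$config$activation,
    config = unclass(model$config),
    trained_on = model$trained_on,
    loss_trace = model$loss_trace,
    W1 = as.vector(t(model$W1)), b1 = model$b1,
    W2 = as.vector(t(model$W2)), b2 = model$b2)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_anomaly_model
#' @export
read_anomaly_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "opposcreen-ae")) {
    abort("Not an opposcreen autoencoder file.",
          class = "opposcreen_format_error")
  }
  cfg <- p$config
  config <- ae_config(cfg$input_dim, cfg$hidden_dim, cfg$epochs,
                      cfg$learning_rate, cfg$batch_size, cfg$seed,
                      cfg$activation, cfg$patience, cfg$tol)
  structure(list(
    W1 = matrix(p$W1, p$input_dim, p$hidden_dim, byrow = TRUE),
    b1 = p$b1,
    W2 = matrix(p$W2, p$hidden_dim, p$input_dim, byrow = TRUE),
    b2 = p$b2,
    config = config, loss_trace = p$loss_trace,
    final_loss = min(p$loss_trace), trained_on = p$trained_on),
    class = "anomaly_model")
}
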