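test_that("the configuration enforces real compression", {
  expect_error(ae_config(input_dim = 10, hidden_dim = 10),
               class = "opposcreen_config_error")
  expect_error(ae_config(input_dim = 10, hidden_dim = 4, epochs = 0),
               class = "opposcreen_config_error")
  cfg <- ae_config(600)
  expect_equal(cfg$hidden_dim, 10L)
})

test_that("an autoencoder memorises a single repeated pattern", {
  set.seed(5)
  v <- runif(50, 0.05, 0.95)
  X <- matrix(rep(v, each = 12), nrow = 12)
  cfg <- ae_config(input_dim = 50, hidden_dim = 4, epochs = 2000,
                   learning_rate = 0.02, seed = 3)
  model <- train_autoencoder(X, cfg)
  expect_lte(model$final_loss, 1e-3)
  expect_lt(model$final_loss, model$loss_trace[1])
})

test_that("training is bitwise deterministic under a fixed seed", {
  set.seed(8)
  X <- matrix(runif(12 * 40), nrow = 12,
              dimnames = list(sprintf("h%02d", 1:12), NULL))
  cfg <- ae_config(input_dim = 40, hidden_dim = 5, epochs = 150, seed = 9)
  m1 <- train_autoencoder(X, cfg)
  m2 <- train_autoencoder(X, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$W1, m2$W1)
  expect_identical(reconstruction_error(m1, X), reconstruction_error(m2, X))
  # a different seed gives a different trajectory
  m3 <- train_autoencoder(X, ae_config(40, 5, epochs = 150, seed = 10))
  expect_false(identical(m1$loss_trace, m3$loss_trace))
})

test_that("reconstruction error is the mean squared componentwise difference", {
  set.seed(2)
  X <- matrix(runif(8 * 30), nrow = 8)
  model <- train_autoencoder(X, ae_config(30, 3, epochs = 50, seed = 1))
  v <- runif(30)
  w <- reconstruct(model, v)
  # independent arithmetic on a component-by-component loop
  acc <- 0
  for (i in seq_along(v)) acc <- acc + (v[i] - w[i])^2
  expect_equal(reconstruction_error(model, v), acc / length(v),
               tolerance = 1e-12)
  expect_gte(reconstruction_error(model, v), 0)
  expect_error(reconstruction_error(model, runif(29)),
               class = "opposcreen_dimension_error")
})

test_that("training rejects bad inputs with informative classes", {
  X <- matrix(runif(6 * 20), nrow = 6)
  expect_error(train_autoencoder(X, ae_config(21, 5, epochs = 10)),
               class = "opposcreen_config_error")
  expect_error(train_autoencoder(X[1, , drop = FALSE],
                                 ae_config(20, 5, epochs = 10)),
               class = "opposcreen_config_error")
  X[2, 3] <- NA
  expect_error(train_autoencoder(X, ae_config(20, 5, epochs = 10)),
               class = "opposcreen_config_error")
})

test_that("scoring excludes the training hands and errors when nothing is left", {
  set.seed(4)
  X <- matrix(runif(20 * 25), nrow = 20,
              dimnames = list(sprintf("h%02d", 1:20), NULL))
  model <- train_autoencoder(X[1:8, ], ae_config(25, 4, epochs = 80, seed = 2))
  sc <- score_cohort(model, X)
  expect_equal(nrow(sc), 12)
  expect_false(any(sc$hand_id %in% model$trained_on))
  expect_true(all(is.finite(sc$mse)) && all(sc$mse >= 0))
  expect_error(score_cohort(model, X[1:8, ]),
               class = "opposcreen_evaluation_error")
  sc_all <- score_cohort(model, X, include_training = TRUE)
  expect_equal(nrow(sc_all), 20)
})

test_that("models round-trip through the portable text format", {
  set.seed(6)
  X <- matrix(runif(10 * 35), nrow = 10,
              dimnames = list(sprintf("h%02d", 1:10), NULL))
  model <- train_autoencoder(X, ae_config(35, 4, epochs = 60, seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_anomaly_model(model, path)
  model2 <- read_anomaly_model(path)
  expect_equal(model2$W1, model$W1, tolerance = 1e-15)
  expect_equal(model2$trained_on, model$trained_on)
  expect_equal(reconstruction_error(model2, X), reconstruction_error(model, X),
               tolerance = 1e-12)
})

test_that("impaired hands score higher than healthy hands on synthetic data", {
  s <- default_cohort_63()
  res <- run_screening(s, seed = 1)
  by_group <- split(res$scores$mse, res$scores$group)
  expect_gt(mean(by_group$cts), mean(by_group$healthy))
  expect_gt(median(by_group$cts), max(0, median(by_group$healthy)))
})

test_that("with zero group effect the score distributions are indistinguishable", {
  # same motor profile for both labels; any detectable difference would be
  # an artefact of the pipeline itself
  failures <- 0L
  for (sd in 1:20) {
    s <- simulate_cohort(50, 50, cts_profile = healthy_profile(),
                         seed = 500 + sd)
    features <- encode_cohort(s)
    meta <- session_meta(s)
    train_ids <- split_training(meta, 12, seed = sd)
    model <- train_autoencoder(features[train_ids, ],
                               ae_config(600, seed = sd))
    sc <- score_cohort(model, features)
    p <- stats::wilcox.test(mse ~ group, data = sc, exact = FALSE)$p.value
    if (p <= 0.01) failures <- failures + 1L
  }
  expect_lte(failures, 2L)
})
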