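test_that("normalized distance is 0 at center, 1 on the circle, clipped beyond", {
  g <- task_geometry()
  expect_equal(normalize_distance(0, 0, g), 0.0)
  expect_equal(normalize_distance(2, 0, g), 1.0)
  expect_equal(normalize_distance(0.6, 0.8, g), 0.5)  # 3-4-5 triangle, 1 cm
  expect_equal(normalize_distance(3, 4, g), 1.0)      # beyond the circle clips
  th <- seq(0, 2 * pi, length.out = 13)
  expect_equal(normalize_distance(2 * cos(th), 2 * sin(th), g), rep(1, 13))
})

test_that("encoded images obey the reach-frame and black-fill rules", {
  g <- task_geometry()

  # instantaneous collection: every row has 1.0 in column 1, 0 elsewhere
  fast <- line_session(duration = 0.05, n_samples = 2)
  img <- encode_image(fast, "H001")
  expect_equal(dim(img), c(12, 50))
  expect_equal(unname(img[, 1]), rep(1, 12))
  expect_equal(sum(img), 12)

  # thumb never moves, nothing collected: all-zero image
  rows <- tibble::as_tibble(line_session(duration = 4.9, n_samples = 50))
  rows$x <- 0; rows$y <- 0; rows$collected <- FALSE
  img <- encode_image(as_sessions(rows), "H001")
  expect_equal(unclass(img), matrix(0, 12, 50), ignore_attr = TRUE)

  # constant-speed 2-s reach ramps linearly 0 -> 1 over 20 frames, then black
  slow <- line_session(duration = 2.0, n_samples = 41)  # samples every 0.05 s
  img <- encode_image(slow, "H001")
  row <- img[5, ]
  expect_equal(row[1:20], seq(0, 1.9, 0.1) / 2, tolerance = 1e-9)
  expect_equal(row[21], 1.0)
  expect_equal(unname(row[22:50]), rep(0, 29))

  # a timed-out trial keeps its observed distances and has no forced white
  rows <- tibble::as_tibble(slow)
  i <- rows$lap == 2 & rows$direction == 3
  rows$collected[i] <- FALSE
  rows$x[i] <- rows$x[i] * 0.6
  rows$y[i] <- rows$y[i] * 0.6
  img2 <- encode_image(as_sessions(rows), "H001")
  expect_lt(max(img2[3, ]), 1.0)
  expect_equal(unname(img2[3, 50]), 0.6, tolerance = 1e-9)
})

test_that("every encoded value lies in [0,1] with an exact post-reach suffix", {
  s <- small_cohort()
  meta <- session_meta(s)
  raw <- tibble::as_tibble(s)
  for (h in meta$hand_id[1:5]) {
    img <- encode_image(s, h)
    expect_true(all(img >= 0 & img <= 1))
    for (d in 1:12) {
      tr <- raw[raw$hand_id == h & raw$lap == 2 & raw$direction == d, ]
      if (nrow(tr) > 0 && tr$collected[1]) {
        f <- min(50, floor(tr$t[nrow(tr)] * 10 + 1e-9) + 1)
        expect_equal(unname(img[d, f]), 1.0)
        if (f < 50) expect_equal(unname(img[d, f + 1]), 0.0)
      }
    }
  }
})

test_that("missing directions yield zero rows and flag the hand", {
  s <- line_session()
  rows <- tibble::as_tibble(s)
  rows <- rows[!(rows$lap == 2 & rows$direction == 9), ]
  img <- encode_image(as_sessions(rows), "H001")
  expect_equal(unname(img[9, ]), rep(0, 50))
  expect_equal(attr(img, "flagged_directions"), 9L)
  expect_error(encode_image(as_sessions(rows[rows$lap == 1, ]), "H001", lap = 2),
               class = "opposcreen_missing_lap_error")
})

test_that("flatten is row-major with the documented index arithmetic", {
  s <- line_session(duration = 0.05, n_samples = 2)
  img <- encode_image(s, "H001")
  v <- flatten(img)
  expect_length(v, 600)
  expect_equal(v, as.vector(t(unclass(img))))

  toy <- matrix(0, 12, 50)
  toy[3, 8] <- 1  # row 3, 8th frame (0-based column 7)
  toy <- structure(toy, geometry = task_geometry())
  vt <- as.vector(t(toy))
  expect_equal(which(vt == 1), (3 - 1) * 50 + 7 + 1)
  expect_equal(flatten(structure(toy, class = c("feature_image", "matrix", "array"))),
               vt)
})

test_that("window slicing wraps around direction 12 and preserves values", {
  s <- line_session(duration = 1.5)
  img <- encode_image(s, "H001")

  w <- slice_window(img, 8, 4)
  expect_length(w, 200)
  expect_equal(w, as.vector(t(unclass(img)[8:11, ])))

  w <- slice_window(img, 12, 4)
  expect_equal(w, as.vector(t(unclass(img)[c(12, 1, 2, 3), ])))

  # full-width window is a cyclic permutation: same multiset of values
  w <- slice_window(img, 5, 12)
  expect_equal(sort(w), sort(flatten(img)))

  expect_error(slice_window(img, 0), class = "opposcreen_domain_error")
  expect_error(slice_window(img, 13), class = "opposcreen_domain_error")
  expect_error(slice_window(img, 1, width = 13),
               class = "opposcreen_domain_error")

  expect_equal(window_label(8), "8-11")
  expect_equal(window_label(12), "12-3")
  expect_equal(window_label(10), "10-1")
})

test_that("feature dimensions follow the geometry for arbitrary task settings", {
  set.seed(11)
  for (i in 1:5) {
    g <- task_geometry(radius = runif(1, 1, 4),
                       n_directions = sample(3:16, 1),
                       timeout = runif(1, 2, 6),
                       sample_rate = sample(c(5, 10, 20), 1))
    s <- simulate_cohort(1, 0, geometry = g, seed = i)
    img <- encode_image(s, "H001", geometry = g)
    expect_equal(dim(img), c(g$n_directions, g$frames_per_trial))
    expect_length(flatten(img), g$n_directions * g$frames_per_trial)
    expect_true(all(img >= 0 & img <= 1))
    wd <- min(4L, g$n_directions)
    expect_length(slice_window(img, 1, wd), wd * g$frames_per_trial)
  }
})

test_that("re-encoding an already-gridded trial is the identity", {
  g <- task_geometry()
  grid <- (0:49) / 10
  # build a trial whose samples sit exactly on the frame grid
  dist <- pmin(grid / 3, 1)
  rows <- tibble::tibble(
    hand_id = "G1", group = "unknown", side = "right",
    severity = NA_integer_, lap = 2L, direction = 1L, collected = FALSE,
    t = grid, x = dist * 2, y = 0)
  for (d in 2:12) {
    rows <- dplyr::bind_rows(rows, dplyr::mutate(rows[1:50, ], direction = d))
  }
  img1 <- encode_image(as_sessions(rows), "G1")
  # feed the encoded row back in as a trial sampled on the same grid
  rows2 <- dplyr::mutate(rows, x = rep(img1[1, ], 12) * 2, y = 0)
  img2 <- encode_image(as_sessions(rows2), "G1")
  expect_equal(unclass(img2), unclass(img1), ignore_attr = TRUE)
})
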