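test_that("envelope filter has unit DC gain and preserves non-negativity", {
  rec <- emg_recording(matrix(1, 6000, 2), 2000)
  env <- compute_envelope(rec)
  expect_equal(tail(env$values[, 1], 1), 1, tolerance = 1e-3)
  expect_true(all(env$values >= 0))

  zero <- compute_envelope(emg_recording(matrix(0, 100, 3) + 0e0, 2000))
  expect_true(all(zero$values == 0))
})

test_that("rectified sinusoid settles to its mean absolute value 2/pi", {
  fs <- 2000
  t <- seq(0, 3, by = 1 / fs)
  rec <- emg_recording(matrix(sin(2 * pi * 100 * t), ncol = 1), fs)
  env <- compute_envelope(rec)
  steady <- tail(env$values[, 1], 1)
  expect_lt(abs(steady - 2 / pi) / (2 / pi), 0.01)
})

test_that("envelope rejects super-Nyquist cutoffs", {
  rec <- emg_recording(matrix(rnorm(100), ncol = 1), 100)
  expect_error(compute_envelope(rec, preprocess_config(cutoff_hz = 60)),
               "Nyquist")
})

test_that("scaler standardises, never leaks, and round trips", {
  set.seed(7)
  pre <- envelope_series(abs(matrix(rnorm(400 * 3, mean = 2), 400)), 2000)
  test <- envelope_series(abs(matrix(rnorm(100 * 3, mean = 5, sd = 3), 100)),
                          2000)
  sc <- fit_scaler(pre)
  z <- apply_scaler(pre, sc)
  expect_equal(colMeans(z$values), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(z$values, 2, sd), rep(1, 3), tolerance = 1e-12)

  # statistics frozen on the fitting corpus, not the transformed series
  expect_equal(sc$center, colMeans(pre$values))
  zt <- apply_scaler(test, sc)
  expect_false(any(abs(colMeans(zt$values)) < 1e-6))

  back <- apply_scaler(zt, sc, invert = TRUE)
  expect_equal(back$values, test$values, tolerance = 1e-12)

  const <- envelope_series(matrix(1, 50, 1), 2000)
  expect_error(fit_scaler(const), "zero-variance")
  expect_error(apply_scaler(envelope_series(matrix(1, 5, 7), 2000), sc),
               "channels")
})

test_that("sliding windows follow the count formula and label convention", {
  set.seed(21)
  n <- 2500
  env <- envelope_series(matrix(rnorm(n * 8), n), 2000)
  labels <- seq_len(n) / 10
  ws <- slide_windows(env, labels, preprocess_config())
  expect_equal(dim(ws$features), c(226L, 250L, 8L))
  # label = velocity at each window's final sample
  ends <- 250L + 10L * (0:225)
  expect_equal(ws$labels, labels[ends])
  expect_equal(ws$window_end_times_s, ends / 2000)

  one <- slide_windows(envelope_series(matrix(0, 250, 2), 2000),
                       rep(0, 250), preprocess_config())
  expect_equal(n_windows(one), 1L)
  expect_error(slide_windows(envelope_series(matrix(0, 249, 2), 2000),
                             rep(0, 249), preprocess_config()),
               "shorter")
  expect_error(slide_windows(env, labels[-1], preprocess_config()),
               "aligned")
})

test_that("window extraction matches a naive double loop on random cases", {
  set.seed(42)
  for (rep in 1:25) {
    wl <- sample(5:30, 1)
    ov <- sample(0:(wl - 1), 1)
    n <- wl + sample(0:150, 1)
    ch <- sample(1:4, 1)
    vals <- matrix(rnorm(n * ch), n)
    labels <- rnorm(n)
    cfg <- preprocess_config(window_len = wl, overlap = ov)
    ws <- slide_windows(envelope_series(vals, 1000), labels, cfg)
    stride <- wl - ov
    expected_count <- (n - wl) %/% stride + 1L
    expect_equal(n_windows(ws), expected_count)
    for (w in seq_len(expected_count)) {
      start <- 1L + (w - 1L) * stride
      expect_identical(ws$features[w, , ],
                       vals[start:(start + wl - 1L), ])
      expect_identical(ws$labels[w], labels[start + wl - 1L])
    }
    # maximality: one more window would overrun the series
    expect_gt(expected_count * stride + wl, n)
  }
})

test_that("window sets concatenate with provenance and persist", {
  a <- slide_windows(envelope_series(matrix(rnorm(600), 300), 2000),
                     rnorm(300), preprocess_config(window_len = 100,
                                                   overlap = 50),
                     subject = "s01", trial = 1)
  b <- slide_windows(envelope_series(matrix(rnorm(600), 300), 2000),
                     rnorm(300), preprocess_config(window_len = 100,
                                                   overlap = 50),
                     subject = "s02", trial = 1)
  both <- bind_window_sets(list(a, b))
  expect_equal(n_windows(both), n_windows(a) + n_windows(b))
  expect_equal(unique(both$subject), c("s01", "s02"))

  p <- tempfile(fileext = ".rds")
  save_window_set(both, p)
  expect_identical(load_window_set(p)$features, both$features)
})

test_that("window duration follows the sampling rate", {
  expect_equal(window_duration_ms(preprocess_config(), 2000), 125)
  expect_equal(window_duration_ms(preprocess_config(window_len = 2000), 2000),
               1000)
  expect_equal(window_duration_ms(preprocess_config(window_len = 1,
                                                    overlap = 0), 1000), 1)
})
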