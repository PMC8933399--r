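test_that("structural normalization follows the direction-average / size-average formula", {
  s <- tractography_sample(matrix(c(0, 14, 10, 0), 2, 2), c(4, 2), c("a", "b"))
  net <- build_structural_connectivity(s)
  expect_equal(net$weights["a", "b"], 4.0)   # ((10+14)/2) / ((4+2)/2)
  expect_equal(diag(net$weights), c(a = 0, b = 0))

  # zero counts -> zero weights; symmetric counts with unit sizes -> identity
  z <- tractography_sample(matrix(0, 4, 4), rep(3, 4))
  expect_true(all(build_structural_connectivity(z)$weights == 0))
  cnt <- random_weights(5, 1, seed = 7) * 10
  s2 <- tractography_sample(cnt, rep(1, 5))
  expect_equal(build_structural_connectivity(s2)$weights, cnt,
               ignore_attr = TRUE)
})

test_that("structural connectivity is transpose-invariant and obeys the size-scaling law", {
  set.seed(21)
  cnt <- matrix(runif(36, 0, 50), 6); diag(cnt) <- 0
  sizes <- runif(6, 200, 2000)
  w1 <- build_structural_connectivity(tractography_sample(cnt, sizes))$weights
  w2 <- build_structural_connectivity(tractography_sample(t(cnt), sizes))$weights
  expect_equal(w1, w2)
  for (c_scale in c(0.5, 3)) {
    w3 <- build_structural_connectivity(tractography_sample(cnt, c_scale * sizes))$weights
    expect_equal(w3, w1 / c_scale)
  }
})

test_that("invalid tractography inputs are rejected", {
  expect_error(tractography_sample(matrix(-1, 2, 2), c(1, 1)), "nonnegative")
  expect_error(tractography_sample(matrix(1, 2, 2), c(1, 0)), "positive")
  expect_error(tractography_sample(matrix(1, 2, 3), c(1, 1)), "square")
})

test_that("band-pass + Hilbert recovers the analytic envelope of test signals", {
  fs <- 150
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  # in-band sinusoid: constant envelope A
  A <- 2.5
  x <- matrix(A * sin(2 * pi * 10 * t), 1)
  ts <- band_timeseries(x, fs, canonical_bands("alpha")[[1]])
  env <- bandpass_and_envelope(ts, "alpha")
  expect_true(all(env$data >= 0))
  expect_lt(max(abs(env$data - A)) / A, 0.01)

  # far out-of-band sinusoid: envelope ~ 0
  x2 <- matrix(sin(2 * pi * 40 * t), 1)
  env2 <- bandpass_and_envelope(band_timeseries(x2, fs, "alpha"), "alpha")
  expect_lt(max(env2$data), 0.01)

  # known slow positive modulator on an in-band carrier is recovered
  m <- 1 + 0.5 * sin(2 * pi * 0.3 * t)
  x3 <- matrix(m * cos(2 * pi * 10 * t), 1)
  env3 <- bandpass_and_envelope(band_timeseries(x3, fs, "alpha"), "alpha")
  ord <- gfnet:::design_bandpass(canonical_bands("alpha")[[1]], fs)$order
  m_trim <- m[(ord + 1):(length(t) - ord)]
  keep <- seq(floor(0.1 * length(m_trim)), ceiling(0.9 * length(m_trim)))
  expect_gt(cor(env3$data[1, keep], m_trim[keep]), 0.95)
})

test_that("the zero-phase filter core matches a direct convolution oracle", {
  set.seed(5)
  b <- as.numeric(signal::fir1(10, c(0.2, 0.5)))
  x <- rnorm(50)
  got <- gfnet:::fir_filtfilt(b, x)
  # oracle: apply stats::filter twice, once reversed (explicit forward-backward)
  pad <- c(rep(0, 20), x, rep(0, 20))
  fwd <- stats::filter(pad, b, method = "convolution", sides = 1)
  bwd <- rev(stats::filter(rev(fwd), b, method = "convolution", sides = 1))
  oracle <- bwd[(20 + 1):(20 + length(x))]
  expect_equal(got, as.numeric(oracle), tolerance = 1e-10)
})

test_that("analytic signal matches the closed form for periodic sinusoids", {
  n <- 256
  t <- 0:(n - 1)
  for (k in c(3, 10, 40)) {
    w <- 2 * pi * k / n        # periodic on the grid: analytic(cos) = exp(iwt)
    a <- gfnet:::analytic_signal(cos(w * t))
    expect_equal(Re(a), cos(w * t), tolerance = 1e-10)
    expect_equal(Im(a), sin(w * t), tolerance = 1e-10)
    expect_equal(Mod(a), rep(1, n), tolerance = 1e-10)
  }
  # linearity
  set.seed(6)
  x <- rnorm(128); y <- rnorm(128)
  expect_equal(gfnet:::analytic_signal(2 * x - 3 * y),
               2 * gfnet:::analytic_signal(x) - 3 * gfnet:::analytic_signal(y),
               tolerance = 1e-10)
})

test_that("band and duration validation errors are informative", {
  fs <- 150
  x <- matrix(rnorm(5 * fs), 1)
  ts <- band_timeseries(x, fs, "alpha")
  expect_error(bandpass_and_envelope(ts, frequency_band("bad", 76, 90)),
               "Nyquist")
  expect_error(bandpass_and_envelope(ts, "delta"), "minimum duration|too short")
})

test_that("envelope-correlation FC has the Pearson contract", {
  fs <- 150
  set.seed(8)
  e1 <- abs(rnorm(600)) + 0.1
  env <- band_timeseries(rbind(e1, e1, 2 * mean(e1) - e1), fs, "alpha",
                         roi_labels = c("a", "b", "c"), envelope = TRUE)
  fc <- build_functional_connectivity(env)
  expect_equal(fc$weights["a", "b"], 1)
  expect_equal(fc$weights["a", "c"], -1)
  expect_equal(diag(fc$weights), setNames(rep(0, 3), c("a", "b", "c")))

  # invariance under positive affine transforms per region
  env2 <- env
  env2$data <- env2$data * c(2, 0.5, 7) + c(1, -3, 100)
  expect_equal(build_functional_connectivity(env2)$weights, fc$weights,
               tolerance = 1e-12)

  # zero-variance region is flagged by name
  env3 <- env
  env3$data[2, ] <- 5
  expect_error(build_functional_connectivity(env3), "b")
})

test_that("independent envelopes give near-zero correlations at long T", {
  set.seed(9)
  n_pairs <- 200
  t_len <- 10000
  r <- replicate(n_pairs, cor(rnorm(t_len), rnorm(t_len)))
  expect_gt(mean(abs(r) < 0.05), 0.99)  # |r| ~< 2/sqrt(T) under the null
})

test_that("matrix and time-series CSV round-trip bit-exactly", {
  w <- random_weights(7, 0.7, seed = 31)
  net <- weighted_network(w, sprintf("R%02d", 1:7), "structural")
  f <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(net, f)
  back <- read_matrix_csv(f, "structural")
  expect_identical(back$weights, net$weights)
  expect_identical(back$roi_labels, net$roi_labels)

  ts <- band_timeseries(matrix(rnorm(3 * 700), 3), 150, "beta")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_timeseries_csv(ts, f2)
  back2 <- read_timeseries_csv(f2)
  expect_identical(back2$data, ts$data)
  expect_equal(back2$fs, 150)
  expect_equal(back2$band$lo, 12)
})
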