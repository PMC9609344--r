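test_that("time-domain features match hand arithmetic", {
  expect_equal(mav(c(0, 0, 0)), 0)
  expect_equal(mav(rep(-3.5, 4)), 3.5)
  expect_equal(mav(c(1, -2, 3)), 2)

  expect_equal(zero_crossings(rep(2, 5)), 0)
  expect_equal(zero_crossings(c(1, -1, 1, -1)), 3)
  # a zero sample breaks both strict inequalities
  expect_equal(zero_crossings(c(1, 0, -1)), 0)

  expect_equal(slope_sign_changes(1:10), 0)
  expect_equal(slope_sign_changes(c(0, 1, 0, 1, 0)), 3)
  expect_equal(slope_sign_changes(rep(1, 5)), 0)

  expect_equal(waveform_length(rep(2, 5)), 0)
  expect_equal(waveform_length(c(0, 1, 3)), 3)
  ramp <- seq(-2, 5, length.out = 40)
  expect_equal(waveform_length(ramp), 7)   # telescoping
})

test_that("scalar features agree with brute-force oracles on random segments", {
  set.seed(42)
  for (i in 1:200) {
    x <- rnorm(sample(30:100, 1))
    eps <- sample(c(0, 0.1), 1)
    expect_equal(mav(x), mav_bf(x))
    expect_equal(zero_crossings(x, eps), zc_bf(x, eps))
    expect_equal(slope_sign_changes(x, eps), ssc_bf(x, eps))
    expect_equal(waveform_length(x), wl_bf(x))
  }
})

test_that("Burg AR fit matches the lattice recursion and recovers known processes", {
  set.seed(7)
  x <- rnorm(300)
  expect_equal(ar_fit(x, 5)$coef, burg_bf(x, 5), tolerance = 1e-10)

  # white noise has no memory
  set.seed(8)
  w <- rnorm(10000)
  expect_true(all(abs(ar_fit(w, 5)$coef) < 0.05))

  # AR(2) recovery, absolute +/- 0.05 band
  set.seed(9)
  x2 <- as.numeric(stats::arima.sim(list(ar = c(0.5, -0.3)), 10000))
  est <- ar_fit(x2, 2)$coef
  expect_lt(abs(est[1] - 0.5), 0.05)
  expect_lt(abs(est[2] + 0.3), 0.05)

  # AR(1) recovery, absolute +/- 0.03
  set.seed(10)
  x1 <- as.numeric(stats::arima.sim(list(ar = 0.9), 10000))
  expect_lt(abs(ar_fit(x1, 1)$coef[1] - 0.9), 0.03)

  # recovery error shrinks with N
  err_at <- function(n, seed) {
    set.seed(seed)
    x <- as.numeric(stats::arima.sim(list(ar = c(0.5, -0.3)), n))
    sqrt(mean((ar_fit(x, 2)$coef - c(0.5, -0.3))^2))
  }
  errs <- vapply(c(500, 5000, 50000), err_at, numeric(1), seed = 11)
  expect_true(errs[3] < errs[1])

  # degenerate input: zero coefficients, flagged
  fit <- ar_fit(rep(0, 100), 5)
  expect_true(fit$degenerate)
  expect_equal(fit$coef, numeric(5))
  expect_error(ar_fit(rnorm(10), 5), "more than 10")
})

test_that("FFT energy obeys Parseval and handles degenerate inputs", {
  expect_equal(unname(fft_features(rep(0, 64))), c(0, 0))
  imp <- c(1, rep(0, 63))
  expect_equal(fft_features(imp)[["energy"]], 1)
  set.seed(12)
  for (i in 1:200) {
    x <- rnorm(sample(20:200, 1))
    f <- fft_features(x)
    expect_equal(f[["energy"]], energy_bf(x), tolerance = 1e-9)
    expect_equal(f[["mean_power"]], energy_bf(x) / length(x),
                 tolerance = 1e-9)
  }
})

test_that("STFT windows partition the energy", {
  z <- stft_features(rep(0, 30))
  expect_equal(unname(z), rep(0, 6))
  expect_length(z, 6)

  set.seed(13)
  for (i in 1:100) {
    x <- rnorm(3 * sample(10:60, 1))    # divisible by 3
    s <- stft_features(x)
    expect_equal(sum(s[c(1, 3, 5)]), fft_features(x)[["energy"]],
                 tolerance = 1e-9)
  }

  # remainder joins the last window
  x <- rnorm(32)
  s <- stft_features(x)
  expect_equal(s[["stft1_energy"]], energy_bf(x[1:10]), tolerance = 1e-12)
  expect_equal(s[["stft3_energy"]], energy_bf(x[21:32]), tolerance = 1e-12)

  # energy concentrated in the first third shows up in window 1
  y <- c(rnorm(100), rnorm(200, sd = 0.01))
  s2 <- stft_features(y)
  expect_gte(s2[["stft1_energy"]], 0.9 * fft_features(y)[["energy"]])
  expect_error(stft_features(c(1, 2)), "at least 3")
})

test_that("db5 wavelet variances match the naive filter bank", {
  expect_equal(dwt_variances(rep(0, 500)), rep(0, 5))
  set.seed(14)
  for (i in 1:50) {
    x <- rnorm(sample(c(100, 250, 500), 1))
    expect_equal(dwt_variances(x), dwt_variances_bf(x), tolerance = 1e-10)
  }
  # constant segment: details vanish away from the boundary (vanishing moments)
  dec <- dwt_db5(rep(3, 256))
  d1 <- dec$detail[[1]]
  interior <- d1[6:(length(d1) - 5)]
  expect_lt(max(abs(interior)), 1e-10)
})

test_that("feature vector has the fixed 20-element layout", {
  set.seed(15)
  x <- rnorm(500)
  v <- extract_features(x)
  expect_length(v, 20)
  expect_identical(names(v), feature_names())
  expect_equal(v[["mav"]], mav(x))
  expect_equal(v[["ar1"]], ar_fit(x, 5)$coef[1])
  expect_equal(unname(v[paste0("v", 1:5)]), dwt_variances(x))

  # zero trial: all zeros (AR degenerates to zero coefficients)
  v0 <- extract_features(rep(0, 500))
  expect_equal(unname(v0), rep(0, 20))
})

test_that("batch extraction builds the 20 x N matrix with labels", {
  set.seed(16)
  windows <- lapply(1:10, function(i)
    structure(list(samples = rnorm(500), label = (i - 1) %% 5,
                   window_bounds = c(start = 1, end = 500), no_burst = FALSE),
              class = "emg_window"))
  fd <- batch_extract(windows)
  expect_s3_class(fd, "feature_dataset")
  expect_equal(dim(fd$X), c(20, 10))
  expect_equal(fd$labels, rep(0:4, 2))
})

test_that("feature CSV round-trips at full precision", {
  set.seed(17)
  windows <- lapply(1:6, function(i)
    structure(list(samples = rnorm(500), label = (i - 1) %% 5,
                   window_bounds = c(start = 1, end = 500), no_burst = FALSE),
              class = "emg_window"))
  fd <- batch_extract(windows)
  path <- tempfile(fileext = ".csv")
  write_features_csv(fd, path)
  back <- read_features_csv(path)
  expect_equal(unname(back$X), unname(fd$X), tolerance = 1e-15)
  expect_equal(back$labels, fd$labels)
  unlink(path)
})

test_that("standardization centers and scales on the training columns only", {
  set.seed(18)
  X <- matrix(rnorm(20 * 30, mean = 5, sd = 3), 20, 30)
  sc <- fit_scaler(X[, 1:20])
  Xs <- apply_scaler(X[, 1:20], sc)
  expect_equal(rowMeans(Xs), rep(0, 20), tolerance = 1e-12)
  expect_equal(apply(Xs, 1, sd), rep(1, 20), tolerance = 1e-12)
  # constant feature: unit scale, no NaN
  X[3, ] <- 2
  sc2 <- fit_scaler(X)
  expect_true(all(is.finite(apply_scaler(X, sc2))))
})
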