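test_that("session accounting is exact", {
  s <- session_stats(60, 1000)
  expect_equal(s$n_samples, 60000)
  expect_equal(s$n_bytes, 120000)
  s2 <- session_stats(0.5, 1000)
  expect_equal(s2$n_samples, 500)
  expect_equal(s2$n_bytes, 1000)
  # exact for arbitrary pairs
  expect_equal(session_stats(12.25, 2000)$n_samples, 24500)
  expect_equal(session_stats(12.25, 2000)$n_bytes, 49000)
  expect_error(session_stats(0), "positive")
})

# helper: digitized trial with a burst of given span (1-based sample indices)
burst_trial <- function(n = 1000, span, seed = 1, label = 0L) {
  set.seed(seed)
  v <- rnorm(n, sd = 0.002)
  v[span] <- v[span] + 0.4 * sin(2 * pi * 80 * seq_along(span) / 1000)
  codes <- pmin(pmax(floor((v + 2.5) / 5 * 1023 + 0.5), 0), 1023)
  structure(list(codes = as.integer(codes), rate = 1000, label = label,
                 n_clipped = 0L, adc = list(bits = 10, v_min = 0, v_max = 5),
                 meta = list(offset_v = 2.5, class = label)),
            class = "digitized_trial")
}

test_that("windowing brackets a mid-trial burst and matches the exhaustive oracle", {
  tr <- burst_trial(1000, span = 301:700, seed = 2)
  w <- window_trial(tr)
  expect_false(w$no_burst)
  expect_length(w$samples, 500)
  # burst center inside the chosen window
  expect_lte(w$window_bounds[["start"]], 500)
  expect_gte(w$window_bounds[["end"]], 500)
  v <- emgpipe:::.restore_volts(tr)
  expect_equal(w$window_bounds[["start"]], best_window_bf(v))
})

test_that("windowing equals the exhaustive search on random bursty trials", {
  # brute-force score of a candidate window (direct sums, no cumsum)
  window_score_bf <- function(v, start, width = 500, frame = 25) {
    e <- v^2
    n <- length(v)
    half <- frame %/% 2
    sum(vapply(start:(start + width - 1), function(i)
      mean(e[max(1, i - half):min(n, i + half)]), numeric(1)))
  }
  for (s in 1:12) {
    start <- sample(1:500, 1)
    tr <- burst_trial(1000, span = start:(start + 199), seed = 100 + s)
    w <- window_trial(tr)
    v <- emgpipe:::.restore_volts(tr)
    best_bf <- best_window_bf(v)
    # the chosen window attains the exhaustive-search maximum (index may
    # differ only on floating-point ties between summation orders)
    s_impl <- window_score_bf(v, w$window_bounds[["start"]])
    s_best <- window_score_bf(v, best_bf)
    expect_gte(s_impl, s_best * (1 - 1e-9))
    if (abs(s_impl - s_best) > 1e-9 * s_best)
      fail(paste("window differs from oracle beyond ties, seed", 100 + s))
  }
})

test_that("a burst at the trial start clamps the window to the first sample", {
  tr <- burst_trial(1000, span = 1:150, seed = 3)
  w <- window_trial(tr)
  expect_equal(w$window_bounds[["start"]], 1)
})

test_that("flat trials get the centered window and the no-burst flag", {
  codes <- rep(512L, 1000)
  tr <- structure(list(codes = codes, rate = 1000, label = 1L,
                       n_clipped = 0L,
                       adc = list(bits = 10, v_min = 0, v_max = 5),
                       meta = list(offset_v = 2.5)),
                  class = "digitized_trial")
  w <- window_trial(tr)
  expect_true(w$no_burst)
  expect_equal(w$window_bounds[["start"]], 251)
  expect_equal(w$samples, rep(0, 500))
})

test_that("short trials are rejected with a length error", {
  tr <- burst_trial(400, span = 100:200)
  expect_error(window_trial(tr), "at least 500")
})

test_that("collect_dataset is class-balanced, order-stable and errors on shortfall", {
  trials <- list()
  for (id in 0:4)
    for (i in 1:3)
      trials <- c(trials, list(burst_trial(1000, span = 201:600,
                                           seed = id * 10 + i, label = id)))
  ds <- collect_dataset(trials, per_class = 3)
  expect_length(ds, 15)
  labs <- vapply(ds, function(w) as.integer(w$label), integer(1))
  expect_equal(as.vector(table(labs)), rep(3L, 5))

  # permutation invariance: shuffled input gives the same multiset of windows
  set.seed(9)
  shuffled <- sample(trials)
  ds2 <- collect_dataset(shuffled, per_class = 3)
  key <- function(w) paste(w$label, paste(signif(w$samples[1:5], 12),
                                          collapse = ","))
  expect_setequal(vapply(ds2, key, character(1)),
                  vapply(ds, key, character(1)))

  expect_error(collect_dataset(trials[-1], per_class = 3), "closed hand")
})

test_that("splits are disjoint, exhaustive and stratified", {
  labels <- rep(0:4, each = 50)
  s <- split_dataset(labels, c(0.6, 0.4), seed = 1)
  expect_length(s$train, 150)
  expect_length(s$validation, 100)
  expect_length(intersect(s$train, s$validation), 0)
  expect_setequal(c(s$train, s$validation), seq_along(labels))
  # stratification: each class split 30/20
  expect_equal(as.vector(table(labels[s$train])), rep(30L, 5))
  expect_equal(as.vector(table(labels[s$validation])), rep(20L, 5))

  s3 <- split_dataset(labels, c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(lengths(s3), c(train = 150L, validation = 50L, test = 50L))
  expect_equal(as.vector(table(labels[s3$test])), rep(10L, 5))

  # per-class proportions within one trial of the request, uneven classes
  labels2 <- rep(0:4, times = c(13, 17, 19, 23, 11))
  s4 <- split_dataset(labels2, c(0.6, 0.4), seed = 2)
  for (id in 0:4) {
    n_id <- sum(labels2 == id)
    n_tr <- sum(labels2[s4$train] == id)
    expect_lte(abs(n_tr - 0.6 * n_id), 1)
  }
})

test_that("identity split, reproducibility and degenerate fractions", {
  labels <- rep(0:4, each = 4)
  s1 <- split_dataset(labels, 1.0, seed = 5)
  expect_setequal(s1$train, seq_along(labels))
  expect_identical(split_dataset(labels, c(0.6, 0.4), seed = 7),
                   split_dataset(labels, c(0.6, 0.4), seed = 7))
  expect_error(split_dataset(labels, c(0.5, 0.4)), "sum to 1")
  # 4 per class at 90/10 leaves an empty validation subset
  expect_error(split_dataset(labels, c(0.9, 0.1), seed = 1), "empty")
})

test_that("manifest records bounds and labels", {
  trials <- lapply(0:4, function(id)
    burst_trial(1000, span = 201:600, seed = id, label = id))
  ds <- collect_dataset(trials, per_class = 1)
  path <- tempfile(fileext = ".csv")
  df <- write_manifest(ds, path)
  expect_true(file.exists(path))
  expect_equal(nrow(df), 5)
  expect_equal(df$class, 0:4)
  unlink(path)
})
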