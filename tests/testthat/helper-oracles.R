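# Independent brute-force oracles. Each deliberately takes the naive route
# (explicit loops, textbook recursions) so agreement with the package's
# vectorized implementations is a genuine two-route check.

mav_bf <- function(x) {
  s <- 0
  for (k in seq_along(x)) s <- s + abs(x[k])
  s / length(x)
}

zc_bf <- function(x, eps = 0) {
  n <- 0L
  for (k in seq_len(length(x) - 1)) {
    if ((x[k] > eps && x[k + 1] < -eps) || (x[k] < -eps && x[k + 1] > eps))
      n <- n + 1L
  }
  n
}

ssc_bf <- function(x, eps = 0) {
  n <- 0L
  for (k in 2:(length(x) - 1)) {
    if ((x[k] > x[k - 1] + eps && x[k] > x[k + 1] + eps) ||
        (x[k] < x[k - 1] - eps && x[k] < x[k + 1] - eps))
      n <- n + 1L
  }
  n
}

wl_bf <- function(x) {
  s <- 0
  for (k in 2:length(x)) s <- s + abs(x[k] - x[k - 1])
  s
}

# Classic Burg lattice recursion (forward/backward prediction errors),
# coefficients in the x(k) = sum a_i x(k-i) + e(k) convention.
burg_bf <- function(x, p) {
  N <- length(x)
  f <- x[2:N]
  b <- x[1:(N - 1)]
  a <- 1
  for (m in 1:p) {
    k <- -2 * sum(f * b) / (sum(f^2) + sum(b^2))
    a <- c(a, 0) + k * rev(c(a, 0))
    if (m < p) {
      f_new <- f[-1] + k * b[-1]
      b_new <- b[-length(b)] + k * f[-length(f)]
      f <- f_new
      b <- b_new
    }
  }
  -a[-1]
}

# Time-domain energy: the Parseval counterpart of the DFT-based feature.
energy_bf <- function(x) sum(x^2)

# Naive db5 analysis step: explicit double loop over output positions and
# filter taps, same boundary convention as the package.
db5_lo_bf <- c(
  0.003335725285001549, -0.012580751999015526, -0.006241490213011705,
  0.077571493840065148, -0.032244869585030480, -0.242294887066190480,
  0.138428145901103120, 0.724308528438574370, 0.603829269797472960,
  0.160102397974125030
)
db5_hi_bf <- rev(db5_lo_bf) * (-1)^seq_along(db5_lo_bf)

dwt_step_bf <- function(x, f) {
  L <- length(f)
  n <- length(x)
  xe <- c(rev(x[seq_len(L - 1)]), x, rev(x[seq(n - L + 2, n)]))
  m <- length(xe) - L + 1
  y <- numeric(m)
  for (i in seq_len(m)) {
    acc <- 0
    for (k in seq_len(L)) acc <- acc + f[k] * xe[i + L - k]
    y[i] <- acc
  }
  y[seq(2, m, by = 2)]
}

dwt_variances_bf <- function(x, levels = 5) {
  a <- x
  v <- numeric(levels)
  for (j in seq_len(levels)) {
    a <- dwt_step_bf(a, db5_lo_bf)
    mu <- sum(a) / length(a)
    v[j] <- sum((a - mu)^2) / (length(a) - 1)
  }
  v
}

var_bf <- function(x) {
  mu <- sum(x) / length(x)
  sum((x - mu)^2) / (length(x) - 1)
}

# Exhaustive windowing oracle: for every candidate start, recompute the
# moving-RMS-smoothed energy sum directly (no cumulative sums).
best_window_bf <- function(v, width = 500, frame = 25) {
  e <- v^2
  n <- length(v)
  half <- frame %/% 2
  sm <- vapply(seq_len(n), function(i)
    mean(e[max(1, i - half):min(n, i + half)]), numeric(1))
  best <- -Inf
  best_start <- 1L
  for (s in seq_len(n - width + 1)) {
    tot <- sum(sm[s:(s + width - 1)])
    if (tot > best + 1e-15) {
      best <- tot
      best_start <- s
    }
  }
  best_start
}

# Amplitude of a bin-aligned tone in a sampled signal, via the DFT.
tone_amplitude <- function(x, freq, rate) {
  n <- length(x)
  k <- round(freq * n / rate)
  2 * Mod(stats::fft(x)[k + 1]) / n
}

# Small synthetic feature dataset for classifier tests (cheap protocol).
make_small_dataset <- function(per_class = 10, seed = 1) {
  run <- run_acquisition_protocol(per_class = per_class, seed = seed)
  run$features
}
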