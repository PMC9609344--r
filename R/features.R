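# The 20-element hybrid feature vector: four time-domain statistics, three
# AR(5) coefficients, FFT energy and mean power, energy and mean power of
# three rectangular STFT windows, and the variances of the five db5
# approximation-coefficient levels.

#' Mean absolute value
#'
#' \eqn{\mathrm{MAV} = \frac{1}{N}\sum_k |x_k|}, the classic EMG intensity
#' feature.
#'
#' @param x numeric segment (mean-centered volts), length >= 1.
#' @return Non-negative scalar.
#' @export
mav <- function(x) {
  if (length(x) < 1) stop("empty segment", call. = FALSE)
  mean(abs(x))
}

#' Zero-crossing count
#'
#' Number of adjacent sample pairs with opposite sign,
#' \eqn{(x_k > \epsilon \wedge x_{k+1} < -\epsilon)} or the mirror
#' condition. The default deadband \eqn{\epsilon = 0} uses strict
#' inequalities, so a sample exactly at zero breaks both conditions;
#' practical EMG work usually sets \eqn{\epsilon > 0} to reject noise.
#'
#' @param x numeric segment, length >= 2.
#' @param eps deadband threshold (default 0).
#' @return Integer count.
#' @export
zero_crossings <- function(x, eps = 0) {
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  a <- x[-length(x)]
  b <- x[-1]
  sum((a > eps & b < -eps) | (a < -eps & b > eps))
}

#' Slope-sign-change count
#'
#' Number of interior samples strictly above or strictly below both
#' neighbours (local extrema), a crude frequency measure. With a deadband
#' the sample must exceed both neighbours by more than `eps`.
#'
#' @param x numeric segment, length >= 3.
#' @param eps deadband threshold (default 0).
#' @return Integer count.
#' @export
slope_sign_changes <- function(x, eps = 0) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  m <- x[2:(n - 1)]
  l <- x[1:(n - 2)]
  r <- x[3:n]
  sum((m > l + eps & m > r + eps) | (m < l - eps & m < r - eps))
}

#' Waveform length
#'
#' Cumulative absolute first difference, \eqn{\sum_k |x_k - x_{k-1}|};
#' mixes amplitude and frequency content.
#'
#' @param x numeric segment, length >= 2.
#' @return Non-negative scalar.
#' @export
waveform_length <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  sum(abs(diff(x)))
}

#' Autoregressive model fit (Burg)
#'
#' Fits \eqn{x(k) = \sum_{i=1}^{P} a_i x(k-i) + e(k)} by Burg's method
#' (stable, no windowing bias; [stats::ar.burg()] backend, no demeaning —
#' segments are already mean-centered). The first three coefficients enter
#' the feature vector. Degenerate (zero-variance) segments return zero
#' coefficients with `degenerate = TRUE` rather than failing.
#'
#' @param x numeric segment, length > 2 * order.
#' @param order model order P (default 5).
#' @return list(order, coef = a_1..a_P, var = residual variance, degenerate).
#' @export
ar_fit <- function(x, order = 5) {
  n <- length(x)
  if (n <= 2 * order)
    stop("need more than ", 2 * order, " samples for AR(", order, ")",
         call. = FALSE)
  if (stats::var(x) < .Machine$double.eps) {
    return(list(order = order, coef = numeric(order), var = 0,
                degenerate = TRUE))
  }
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = FALSE)
  list(order = order, coef = as.numeric(fit$ar), var = fit$var.pred,
       degenerate = FALSE)
}

#' FFT energy and mean power
#'
#' Energy in the Parseval-consistent convention
#' \eqn{E = \frac{1}{N}\sum_k |X_k|^2 = \sum_n x_n^2} and mean power
#' \eqn{P = E / N}, computed from the DFT so the time-domain identity acts
#' as an independent check.
#'
#' @param x numeric segment, length >= 1.
#' @return c(energy, mean_power).
#' @export
fft_features <- function(x) {
  n <- length(x)
  if (n < 1) stop("empty segment", call. = FALSE)
  energy <- sum(Mod(stats::fft(x))^2) / n
  c(energy = energy, mean_power = energy / n)
}

#' Rectangular-window STFT energy and mean power
#'
#' Partitions the segment into `n_windows` contiguous rectangular windows
#' (the remainder joins the last window) and computes [fft_features()] per
#' window. With disjoint rectangular windows the window energies sum to the
#' total FFT energy.
#'
#' @param x numeric segment, length >= `n_windows`.
#' @param n_windows number of time windows (default 3).
#' @return Named vector of `2 * n_windows` values
#'   (energy, mean_power per window).
#' @export
stft_features <- function(x, n_windows = 3) {
  n <- length(x)
  if (n < n_windows)
    stop("need at least ", n_windows, " samples", call. = FALSE)
  base <- n %/% n_windows
  out <- numeric(0)
  for (w in seq_len(n_windows)) {
    from <- (w - 1) * base + 1
    to <- if (w == n_windows) n else w * base
    fw <- fft_features(x[from:to])
    out <- c(out, fw)
  }
  names(out) <- as.vector(t(outer(seq_len(n_windows),
                                  c("energy", "mean_power"),
                                  function(w, s) paste0("stft", w, "_", s))))
  out
}

#' Variances of db5 approximation coefficients
#'
#' Five-level db5 multiresolution analysis of the segment; returns the
#' sample variance (denominator N-1) of the approximation coefficient
#' vector at each level.
#'
#' @param x numeric segment (see [dwt_db5()] for the length requirement).
#' @param levels decomposition depth (default 5).
#' @param branch `"approx"` (default) or `"detail"` coefficients.
#' @return Numeric vector `v_1..v_levels`.
#' @export
dwt_variances <- function(x, levels = 5, branch = c("approx", "detail")) {
  branch <- match.arg(branch)
  dec <- dwt_db5(x, levels = levels)
  vapply(dec[[branch]], stats::var, numeric(1))
}

#' Names of the 20 features, in vector order
#' @return character vector of length 20.
#' @export
feature_names <- function() {
  c("mav", "zc", "ssc", "wl", "ar1", "ar2", "ar3",
    "fft_energy", "fft_mean_power",
    "stft1_energy", "stft1_mean_power",
    "stft2_energy", "stft2_mean_power",
    "stft3_energy", "stft3_mean_power",
    paste0("v", 1:5))
}

#' Extract the 20-element hybrid feature vector
#'
#' Fixed order: MAV, ZC, SSC, WL, AR(5) coefficients 1-3, FFT energy and
#' mean power, (energy, mean power) for STFT windows 1-3, db5
#' approximation-coefficient variances v1-v5.
#'
#' @param x an `emg_window` or a plain numeric segment (mean-centered).
#' @param eps ZC/SSC deadband (default 0).
#' @return Named numeric vector of length 20.
#' @export
extract_features <- function(x, eps = 0) {
  seg <- if (inherits(x, "emg_window")) x$samples else as.numeric(x)
  ar <- ar_fit(seg, order = 5)
  out <- c(
    mav(seg),
    zero_crossings(seg, eps),
    slope_sign_changes(seg, eps),
    waveform_length(seg),
    ar$coef[1:3],
    fft_features(seg),
    stft_features(seg, 3),
    dwt_variances(seg, 5)
  )
  names(out) <- feature_names()
  out
}

#' Batch feature extraction
#'
#' @param windows list of `emg_window` objects (or numeric segments with a
#'   `labels` argument).
#' @param labels optional integer labels overriding the windows' own.
#' @param eps ZC/SSC deadband.
#' @return A `feature_dataset`: `X` (20 x N matrix, features in rows),
#'   `labels` (integer vector length N), `feature_names`.
#' @export
batch_extract <- function(windows, labels = NULL, eps = 0) {
  X <- vapply(windows, extract_features, numeric(20), eps = eps)
  if (is.null(labels)) {
    labels <- vapply(windows, function(w)
      as.integer(if (inherits(w, "emg_window")) w$label else NA), integer(1))
  }
  rownames(X) <- feature_names()
  structure(list(X = X, labels = as.integer(labels),
                 feature_names = feature_names()),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> %d x %d (features x trials), classes: %s\n",
              nrow(x$X), ncol(x$X),
              paste(sort(unique(x$labels)), collapse = " ")))
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' Columns `f01..f20,label`, one row per trial; full-precision round trip.
#'
#' @param fd a `feature_dataset`.
#' @param path CSV path.
#' @return `path` invisibly (write); a `feature_dataset` (read).
#' @export
write_features_csv <- function(fd, path) {
  stopifnot(inherits(fd, "feature_dataset"))
  df <- as.data.frame(t(fd$X))
  names(df) <- sprintf("f%02d", seq_len(nrow(fd$X)))
  df$label <- fd$labels
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path)
  lab <- df$label
  X <- t(as.matrix(df[setdiff(names(df), "label")]))
  rownames(X) <- feature_names()[seq_len(nrow(X))]
  structure(list(X = X, labels = as.integer(lab),
                 feature_names = rownames(X)),
            class = "feature_dataset")
}

#' Fit / apply per-feature standardization
#'
#' Z-scores each feature using statistics of the training columns only.
#' Zero-variance features get unit scale. Sigmoid-activated networks need
#' inputs on a common scale; the scaler is stored with the trained model
#' and reapplied at prediction time.
#'
#' @param X 20 x N feature matrix (training columns only).
#' @return list(center, scale) of per-feature statistics.
#' @export
fit_scaler <- function(X) {
  ctr <- rowMeans(X)
  sc <- apply(X, 1, stats::sd)
  sc[sc < .Machine$double.eps] <- 1
  list(center = ctr, scale = sc)
}

#' @rdname fit_scaler
#' @param scaler a fitted scaler.
#' @export
apply_scaler <- function(X, scaler) {
  (X - scaler$center) / scaler$scale
}
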