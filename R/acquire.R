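# Acquisition protocol: 1 kHz sessions, windowing to the 500-sample region
# of interest, dataset bookkeeping and stratified splits.

#' Session sample/byte accounting
#'
#' Exact accounting of a serial acquisition session: `rate * duration`
#' samples, two bytes per sample on the wire (a 60 s, 1 kHz session is
#' 60,000 samples, 120,000 bytes).
#'
#' @param duration session length in seconds (> 0).
#' @param rate sampling rate in Hz.
#' @param bytes_per_sample wire width (default 2).
#' @return list(duration, n_samples, n_bytes).
#' @export
session_stats <- function(duration, rate = 1000, bytes_per_sample = 2) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  n <- rate * duration
  list(duration = duration, n_samples = n, n_bytes = bytes_per_sample * n)
}

# Codes back to volts at the ADC input, offset removed, mean-centered.
# Zero-crossing style features are meaningless on unsigned offset codes.
.restore_volts <- function(trial) {
  adc <- trial$adc
  v <- trial$codes / (2^adc$bits - 1) * (adc$v_max - adc$v_min) + adc$v_min
  off <- trial$meta$offset_v
  if (!is.null(off)) v <- v - off
  v - mean(v)
}

#' Window a trial to its region of interest
#'
#' Selects the `width`-sample window with maximal contraction energy,
#' discarding the quiescent part of the recording. Sample energies are
#' smoothed with a moving average over `frame`-sample frames (a moving-RMS
#' detector) and the window maximizing total smoothed energy is kept; ties
#' break to the earliest start. Trials with no discernible burst (flat
#' energy profile) return the centered window with `no_burst = TRUE`.
#'
#' @param trial a `digitized_trial` with at least `width` samples.
#' @param width window length in samples (default 500).
#' @param frame moving-RMS frame length in samples (default 25).
#' @return An `emg_window`: `samples` (volts, offset removed,
#'   mean-centered), `label`, `window_bounds` (1-based inclusive start/end),
#'   `no_burst`.
#' @export
window_trial <- function(trial, width = 500, frame = 25) {
  stopifnot(inherits(trial, "digitized_trial"))
  n <- length(trial$codes)
  if (n < width)
    stop("trial has ", n, " samples; windowing needs at least ", width,
         call. = FALSE)
  v <- .restore_volts(trial)
  e <- v^2
  # centered moving average with partial frames at the edges, so boundary
  # bursts are not penalized
  half <- frame %/% 2
  ce <- c(0, cumsum(e))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  sm <- (ce[hi + 1] - ce[lo]) / (hi - lo + 1)
  # total smoothed energy of every width-length window, via cumulative sums
  cs <- c(0, cumsum(sm))
  score <- cs[(width + 1):(n + 1)] - cs[1:(n - width + 1)]
  no_burst <- max(score) <= 0 ||
    (max(score) - min(score)) < 1e-10 * max(score)
  start <- if (no_burst) (n - width) %/% 2 + 1 else which.max(score)
  end <- start + width - 1L
  structure(
    list(samples = v[start:end], label = trial$label,
         window_bounds = c(start = start, end = end), no_burst = no_burst),
    class = "emg_window"
  )
}

#' @export
print.emg_window <- function(x, ...) {
  cat(sprintf("<emg_window> %d samples, label %s, bounds [%d, %d]%s\n",
              length(x$samples), if (is.null(x$label)) "NA" else x$label,
              x$window_bounds[1], x$window_bounds[2],
              if (x$no_burst) ", no burst" else ""))
  invisible(x)
}

#' Collect a class-balanced windowed dataset
#'
#' Groups digitized trials by gesture label (stable within class), checks
#' that every class has at least `per_class` trials, and windows the first
#' `per_class` of each. The full protocol (50 per class) yields 250 windowed
#' trials.
#'
#' @param trials list of `digitized_trial` objects with labels 0-4.
#' @param per_class trials to keep per class.
#' @param width,frame windowing parameters, see [window_trial()].
#' @return List of `5 * per_class` `emg_window` objects ordered by class.
#' @export
collect_dataset <- function(trials, per_class = 50, width = 500, frame = 25) {
  labels <- vapply(trials, function(tr) as.integer(tr$label), integer(1))
  out <- vector("list", 5L * per_class)
  k <- 0L
  for (id in 0:4) {
    idx <- which(labels == id)
    if (length(idx) < per_class)
      stop("class '", gesture_name(id), "' has ", length(idx),
           " trials; protocol needs ", per_class, call. = FALSE)
    for (i in idx[seq_len(per_class)]) {
      k <- k + 1L
      out[[k]] <- window_trial(trials[[i]], width = width, frame = frame)
    }
  }
  out
}

#' Stratified dataset split
#'
#' Partitions indices into disjoint, exhaustive subsets stratified by class,
#' with per-class counts assigned by largest-remainder rounding so the class
#' proportions match the requested fractions to within one trial.
#' Reproducible for a given seed. Two fractions give train/validation (the
#' headline 60/40 protocol); three give train/validation/test (60/20/20).
#'
#' @param labels integer class labels (0-4), one per trial/vector.
#' @param fractions numeric vector summing to 1 (length 1-3).
#' @param seed integer seed for the within-class shuffle.
#' @return Named list of integer index vectors (`train`, `validation`,
#'   `test` as applicable).
#' @export
split_dataset <- function(labels, fractions = c(0.6, 0.4), seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)
  nm <- switch(length(fractions),
               "train",
               c("train", "validation"),
               c("train", "validation", "test"))
  if (is.null(nm)) stop("between 1 and 3 fractions supported", call. = FALSE)
  labels <- as.integer(labels)
  parts <- stats::setNames(vector("list", length(fractions)), nm)
  set.seed(as.integer(seed))
  for (id in unique(sort(labels))) {
    idx <- sample(which(labels == id))
    n <- length(idx)
    exact <- fractions * n
    counts <- floor(exact)
    rem <- n - sum(counts)
    if (rem > 0) {
      order_rem <- order(exact - counts, decreasing = TRUE)
      counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1
    }
    if (any(counts == 0))
      stop("fractions leave an empty subset for class ", id, call. = FALSE)
    at <- 0
    for (j in seq_along(counts)) {
      parts[[j]] <- c(parts[[j]], idx[at + seq_len(counts[j])])
      at <- at + counts[j]
    }
  }
  lapply(parts, sort)
}

#' Write a dataset manifest
#'
#' CSV index of windowed trials: trial id, class id and name, window bounds
#' and the no-burst flag.
#'
#' @param windows list of `emg_window` objects.
#' @param path output CSV path.
#' @return The manifest data.frame, invisibly.
#' @export
write_manifest <- function(windows, path) {
  df <- data.frame(
    trial_id = seq_along(windows),
    class = vapply(windows, function(w) as.integer(w$label), integer(1)),
    window_start = vapply(windows, function(w) w$window_bounds[[1]], numeric(1)),
    window_end = vapply(windows, function(w) w$window_bounds[[2]], numeric(1)),
    no_burst = vapply(windows, function(w) w$no_burst, logical(1))
  )
  df$gesture <- gesture_name(df$class)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
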