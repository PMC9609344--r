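# Synthetic surface-EMG generation.
#
# Real surface EMG is a stochastic interference pattern: sub-10 mV bipolar,
# usable energy below 500 Hz, dominant energy at 50-150 Hz, organised into
# contraction bursts. The generator reproduces exactly those gross
# statistics — band-limited Gaussian carrier noise under a smooth
# raised-cosine contraction envelope — without claiming physiological
# fidelity (no motor-unit model, single channel only).

# Class-conditional structure. The five gestures are made statistically
# separable through envelope peak amplitude, burst count, and the tilt of
# the carrier band within the 50-150 Hz dominant range.
.class_profiles <- function() {
  data.frame(
    id = 0:4,
    peak_mv = c(2.4, 1.9, 1.4, 1.0, 0.7),
    n_bursts = c(1L, 2L, 3L, 1L, 2L),
    band_lo = c(55, 65, 75, 85, 95),
    band_hi = c(110, 120, 130, 140, 145)
  )
}

#' Parameters for the synthetic EMG generator
#'
#' @param seed integer seed; mandatory, every trial is a pure function of
#'   (class, seed).
#' @param internal_rate simulation rate in Hz. 10 kHz leaves headroom above
#'   the 0-500 Hz EMG band before the 1 kHz ADC stage.
#' @param trial_duration trial length in seconds. The default 1 s yields
#'   1000 digitized points at 1 kHz, from which the 500-point region of
#'   interest is windowed.
#' @param peak_scale multiplier on the per-class envelope peak amplitudes
#'   (set to 0 for a silent trace).
#' @param mains_amplitude amplitude in mV of additive mains interference
#'   (0 disables).
#' @param mains_hz mains frequency in Hz (default 60).
#' @param wander_amplitude amplitude in mV of sub-20 Hz baseline wander
#'   (0 disables).
#' @param wander_hz baseline wander frequency in Hz, must be below 20.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(seed,
                         internal_rate = 10000,
                         trial_duration = 1,
                         peak_scale = 1,
                         mains_amplitude = 0,
                         mains_hz = 60,
                         wander_amplitude = 0,
                         wander_hz = 5) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is mandatory for reproducible trials", call. = FALSE)
  if (trial_duration <= 0)
    stop("trial_duration must be positive", call. = FALSE)
  if (wander_hz >= 20)
    stop("baseline wander frequency must be below 20 Hz", call. = FALSE)
  structure(
    list(seed = as.integer(seed), internal_rate = internal_rate,
         trial_duration = trial_duration, peak_scale = peak_scale,
         mains_amplitude = mains_amplitude, mains_hz = mains_hz,
         wander_amplitude = wander_amplitude, wander_hz = wander_hz),
    class = "synth_params"
  )
}

#' Construct an analog signal object
#'
#' A bipolar voltage trace at a stated rate, the exchange format of the
#' generator and the conditioning chain.
#'
#' @param samples numeric vector of voltages (V).
#' @param rate sampling rate in Hz.
#' @param meta optional provenance list.
#' @return An object of class `emg_analog`.
#' @export
analog_signal <- function(samples, rate, meta = list()) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), rate > 0)
  structure(list(samples = as.numeric(samples), rate = rate, meta = meta),
            class = "emg_analog")
}

#' @export
print.emg_analog <- function(x, ...) {
  cat(sprintf("<emg_analog> %d samples @ %g Hz, peak %.3g mV\n",
              length(x$samples), x$rate, 1000 * max(abs(x$samples))))
  invisible(x)
}

# Raised-cosine contraction envelope, in volts. Burst centres are spread
# over the middle of the trial; a 5%-of-peak tonic floor keeps the trace
# from being exactly silent between bursts while still vanishing when the
# peak is zero.
.contraction_envelope <- function(n, rate, n_bursts, peak_v) {
  t <- (seq_len(n) - 1) / rate
  dur <- n / rate
  centers <- dur * seq_len(n_bursts) / (n_bursts + 1)
  half_width <- 0.30 * dur / n_bursts
  env <- rep(0.05, n)
  for (c0 in centers) {
    u <- (t - c0) / half_width
    inside <- abs(u) < 1
    env[inside] <- pmax(env[inside], 0.5 * (1 + cos(pi * u[inside])))
  }
  peak_v * env
}

# Band-limited Gaussian carrier, shaped in the frequency domain with a
# squared-cosine taper 5 Hz wide inside each band edge, normalised to unit
# peak so the envelope alone sets the amplitude.
.band_noise <- function(n, rate, lo, hi) {
  w <- stats::rnorm(n)
  f <- seq(0, rate, length.out = n + 1)[seq_len(n)]
  f <- ifelse(f > rate / 2, rate - f, f)   # fold to physical frequency
  taper_w <- 5
  g <- numeric(n)
  inband <- f >= lo & f <= hi
  g[inband] <- 1
  ramp_lo <- f >= lo & f < lo + taper_w
  g[ramp_lo] <- sin(0.5 * pi * (f[ramp_lo] - lo) / taper_w)^2
  ramp_hi <- f > hi - taper_w & f <= hi
  g[ramp_hi] <- sin(0.5 * pi * (hi - f[ramp_hi]) / taper_w)^2
  x <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / n
  m <- max(abs(x))
  if (m > 0) x / m else x
}

.trial_seed <- function(seed, id) {
  as.integer((as.numeric(seed) + 7919 * (id + 1)) %% 2147483647)
}

#' Generate one synthetic EMG trial
#'
#' Band-limited Gaussian noise in the class-specific carrier band,
#' multiplied by a raised-cosine contraction envelope with a class-specific
#' burst count and peak amplitude. Deterministic for a given (class, seed):
#' repeated calls return bit-identical traces. Mains interference and
#' baseline wander are added when their amplitudes are non-zero.
#'
#' @param cls gesture class id (0-4) or name.
#' @param params a [synth_params()] object.
#' @return An [analog_signal()] at `params$internal_rate`.
#' @export
#' @examples
#' sig <- generate_trial("grip", synth_params(seed = 7))
#' max(abs(sig$samples)) < 10e-3   # sub-10 mV contract
generate_trial <- function(cls, params) {
  id <- gesture_id(cls)
  stopifnot(inherits(params, "synth_params"))
  prof <- .class_profiles()[id + 1L, ]
  n <- round(params$internal_rate * params$trial_duration)
  if (n < 2) stop("trial_duration too short for the internal rate", call. = FALSE)

  set.seed(.trial_seed(params$seed, id))
  peak_v <- 1e-3 * prof$peak_mv * params$peak_scale
  x <- .band_noise(n, params$internal_rate, prof$band_lo, prof$band_hi) *
    .contraction_envelope(n, params$internal_rate, prof$n_bursts, peak_v)

  sig <- analog_signal(x, params$internal_rate,
                       meta = list(class = id, seed = params$seed,
                                   gesture = gesture_name(id)))
  if (params$mains_amplitude > 0)
    sig <- add_interference(sig, params$mains_hz, params$mains_amplitude)
  if (params$wander_amplitude > 0)
    sig <- add_baseline_wander(sig, params$wander_hz, params$wander_amplitude)
  sig
}

#' Add mains interference to a signal
#'
#' Adds a pure sinusoid at the mains frequency. The original trace is
#' recoverable by subtracting the same sinusoid.
#'
#' @param sig an [analog_signal()].
#' @param mains_hz interference frequency in Hz.
#' @param amp_mv amplitude in millivolts.
#' @return The contaminated [analog_signal()].
#' @export
add_interference <- function(sig, mains_hz = 60, amp_mv = 1) {
  stopifnot(inherits(sig, "emg_analog"))
  if (amp_mv == 0) return(sig)
  t <- (seq_along(sig$samples) - 1) / sig$rate
  sig$samples <- sig$samples + 1e-3 * amp_mv * sin(2 * pi * mains_hz * t)
  sig
}

#' Add baseline wander
#'
#' Adds a slow sinusoidal drift emulating cable/electrode movement, whose
#' energy the 20 Hz high-pass stage is designed to remove. The wander
#' frequency must therefore be below 20 Hz.
#'
#' @param sig an [analog_signal()].
#' @param f_hz wander frequency in Hz, strictly below 20.
#' @param amp_mv amplitude in millivolts.
#' @return The contaminated [analog_signal()].
#' @export
add_baseline_wander <- function(sig, f_hz = 5, amp_mv = 1) {
  stopifnot(inherits(sig, "emg_analog"))
  if (f_hz >= 20)
    stop("baseline wander frequency must be below 20 Hz", call. = FALSE)
  if (amp_mv == 0) return(sig)
  t <- (seq_along(sig$samples) - 1) / sig$rate
  sig$samples <- sig$samples + 1e-3 * amp_mv * sin(2 * pi * f_hz * t)
  sig
}

#' Generate a labeled acquisition session
#'
#' Produces `per_class_trials` trials for each of the five gestures (the
#' full protocol is 50 per class, 250 trials). Each trial gets a distinct
#' seed derived deterministically from the session seed, so the whole
#' session is reproducible.
#'
#' @param per_class_trials trials per gesture class (>= 1).
#' @param params a [synth_params()] object; its seed anchors the session.
#' @return A list of `5 * per_class_trials` elements, each
#'   `list(signal = <emg_analog>, class = <id>)`, grouped by class.
#' @export
generate_session <- function(per_class_trials = 50, params) {
  stopifnot(inherits(params, "synth_params"))
  if (per_class_trials < 1) stop("per_class_trials must be >= 1", call. = FALSE)
  out <- vector("list", 5L * per_class_trials)
  k <- 0L
  for (id in 0:4) {
    for (i in seq_len(per_class_trials)) {
      p <- params
      p$seed <- as.integer((as.numeric(params$seed) + 101 * (k + 1)) %% 2147483647)
      k <- k + 1L
      sig <- generate_trial(id, p)
      sig$meta$trial <- i
      out[[k]] <- list(signal = sig, class = id)
    }
  }
  out
}

#' Write a trial to CSV with a JSON sidecar
#'
#' Single-column CSV of voltages plus a `<path>.json` sidecar recording the
#' rate, class and seed.
#'
#' @param sig an [analog_signal()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(sig, path) {
  stopifnot(inherits(sig, "emg_analog"))
  utils::write.table(data.frame(volts = sig$samples), path,
                     sep = ",", row.names = FALSE, col.names = TRUE)
  side <- c(list(rate = sig$rate), sig$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trial written by [write_trial_csv()]
#'
#' @param path CSV path (expects the `.json` sidecar next to it).
#' @return An [analog_signal()].
#' @export
read_trial_csv <- function(path) {
  v <- utils::read.csv(path)$volts
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  analog_signal(v, side$rate, meta = side[setdiff(names(side), "rate")])
}
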