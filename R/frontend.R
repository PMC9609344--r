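# Digital emulation of the analog conditioning chain: instrumentation
# pre-amplifier, 3rd-order Butterworth low-pass (500 Hz design / 471 Hz
# realized) and high-pass (20 Hz design / 22.7 Hz realized), non-inverting
# final gain, DC offset to ADC mid-range, and a 10-bit 0-5 V ADC at 1 kHz.

#' Instrumentation amplifier gain
#'
#' Gain of the three-op-amp instrumentation stage,
#' \eqn{G = (R_4/R_3)\,(2 R_2/R_1 + 1)}, applied to the differential input
#' \eqn{v_2 - v_1}. With \eqn{R_3 = R_4} and \eqn{R_2/R_1 = 15} the tuned
#' pre-amplification gain of 31 is obtained.
#'
#' @param R1,R2,R3,R4 resistances in ohms; all must be positive except `R2`,
#'   which may be zero (gain collapses to \eqn{R_4/R_3}).
#' @return Dimensionless gain.
#' @export
#' @examples
#' instrumentation_gain(R1 = 1, R2 = 15, R3 = 1, R4 = 1)  # 31
instrumentation_gain <- function(R1, R2, R3, R4) {
  if (R1 <= 0) stop("R1 must be positive", call. = FALSE)
  if (R3 <= 0) stop("R3 must be positive", call. = FALSE)
  if (R4 <= 0 || R2 < 0) stop("resistances must be non-negative (R4 positive)",
                              call. = FALSE)
  (R4 / R3) * (2 * R2 / R1 + 1)
}

#' Analytic 3rd-order Butterworth frequency response
#'
#' Complex response of the normalized 3rd-order Butterworth prototype
#' \eqn{H(s) = 1/(s^3 + 2s^2 + 2s + 1)} evaluated at \eqn{s = j f/f_c}
#' (low-pass) or its \eqn{s \to 1/s} transform (high-pass). The magnitude is
#' \eqn{|H| = 1/\sqrt{1 + (f/f_c)^{6}}} for the low-pass, giving the
#' maximally flat passband, -3.01 dB at \eqn{f_c} and a 60 dB/decade
#' asymptote.
#'
#' @param f frequencies in Hz (vector; may be signed for FFT-bin use).
#' @param fc cutoff frequency in Hz.
#' @param kind `"lowpass"` or `"highpass"`.
#' @return Complex response values, same length as `f`.
#' @export
butter3_response <- function(f, fc, kind = c("lowpass", "highpass")) {
  kind <- match.arg(kind)
  s <- 1i * f / fc
  if (kind == "highpass") {
    num <- s^3
  } else {
    num <- rep(1 + 0i, length(f))
  }
  h <- num / (s^3 + 2 * s^2 + 2 * s + 1)
  if (kind == "highpass") h[f == 0] <- 0 + 0i
  h
}

#' Apply a 3rd-order Butterworth filter
#'
#' Two realizations are available. `"analog"` (default) applies the exact
#' analog prototype response [butter3_response()] in the frequency domain,
#' so the realized magnitude equals the analytic Butterworth curve at every
#' resolvable frequency. `"bilinear"` designs a digital IIR via the bilinear
#' transform ([signal::butter()]) and filters causally, emulating sample-by-
#' sample real-time behaviour at the cost of frequency warping near Nyquist.
#'
#' @param sig an [analog_signal()].
#' @param fc cutoff frequency in Hz; must be below `sig$rate / 2`.
#' @param kind `"lowpass"` or `"highpass"`.
#' @param method `"analog"` or `"bilinear"`.
#' @return The filtered [analog_signal()].
#' @export
butterworth3 <- function(sig, fc, kind = c("lowpass", "highpass"),
                         method = c("analog", "bilinear")) {
  stopifnot(inherits(sig, "emg_analog"))
  kind <- match.arg(kind)
  method <- match.arg(method)
  if (fc >= sig$rate / 2)
    stop("cutoff must be below the Nyquist frequency ", sig$rate / 2, " Hz",
         call. = FALSE)
  n <- length(sig$samples)
  if (method == "analog") {
    k <- seq_len(n) - 1
    f <- k * sig$rate / n
    f[f > sig$rate / 2] <- f[f > sig$rate / 2] - sig$rate   # signed bins
    h <- butter3_response(f, fc, kind)
    sig$samples <- Re(stats::fft(stats::fft(sig$samples) * h, inverse = TRUE)) / n
  } else {
    ba <- signal::butter(3, fc / (sig$rate / 2),
                         type = if (kind == "lowpass") "low" else "high")
    sig$samples <- as.numeric(signal::filter(ba, sig$samples))
  }
  sig
}

#' Non-inverting amplifier stage
#'
#' Gain \eqn{1 + r_{fb}/r_{in}}, the second amplification stage. The
#' hardware design spans gains 1-30 (20 kohm potentiometer); requests
#' outside that range are clamped with a warning.
#'
#' @param sig an [analog_signal()].
#' @param r_fb feedback resistance (ohms, >= 0).
#' @param r_in input resistance (ohms, > 0).
#' @return The amplified [analog_signal()].
#' @export
noninverting_gain <- function(sig, r_fb, r_in) {
  stopifnot(inherits(sig, "emg_analog"))
  if (r_in <= 0) stop("r_in must be positive", call. = FALSE)
  g <- 1 + r_fb / r_in
  if (g < 1 || g > 30) {
    warning("non-inverting gain ", signif(g, 4),
            " outside the design range [1, 30]; clamped")
    g <- min(max(g, 1), 30)
  }
  sig$samples <- g * sig$samples
  sig
}

#' Offset stage (non-inverting summing amplifier)
#'
#' Shifts the bipolar conditioned signal by `v_ref` so it sits inside the
#' unipolar 0-5 V ADC range. Default 2.5 V (ADC mid-scale); the tuned
#' hardware alternative is 1.5 V.
#'
#' @param sig an [analog_signal()].
#' @param v_ref offset voltage in volts.
#' @return The shifted [analog_signal()].
#' @export
offset_stage <- function(sig, v_ref = 2.5) {
  stopifnot(inherits(sig, "emg_analog"))
  sig$samples <- sig$samples + v_ref
  sig$meta$offset_v <- v_ref
  sig
}

#' ADC quantization and decimation
#'
#' Decimates to the ADC rate (the low-pass stage already bounds content
#' below 500 Hz) and maps voltages in `[v_min, v_max]` to the nearest code
#' in `[0, 2^bits - 1]` under round-half-up. Out-of-range samples saturate;
#' the clip count is reported, not fatal.
#'
#' @param sig an [analog_signal()] whose rate is an integer multiple of `rate`.
#' @param bits ADC resolution (default 10).
#' @param v_min,v_max conversion range in volts (default 0-5).
#' @param rate output sampling rate in Hz (default 1000).
#' @return A `digitized_trial`: integer `codes`, `rate`, `label`,
#'   `n_clipped`, `adc` spec and provenance `meta`.
#' @export
adc_quantize <- function(sig, bits = 10, v_min = 0, v_max = 5, rate = 1000) {
  stopifnot(inherits(sig, "emg_analog"))
  dec <- sig$rate / rate
  if (abs(dec - round(dec)) > 1e-9)
    stop("signal rate must be an integer multiple of the ADC rate", call. = FALSE)
  v <- sig$samples[seq(1, length(sig$samples), by = round(dec))]
  full <- 2^bits - 1
  codes <- floor((v - v_min) / (v_max - v_min) * full + 0.5)
  n_clipped <- sum(codes < 0 | codes > full)
  codes <- pmin(pmax(codes, 0), full)
  structure(
    list(codes = as.integer(codes), rate = rate,
         label = sig$meta$class, n_clipped = n_clipped,
         adc = list(bits = bits, v_min = v_min, v_max = v_max),
         meta = sig$meta),
    class = "digitized_trial"
  )
}

#' @export
print.digitized_trial <- function(x, ...) {
  cat(sprintf("<digitized_trial> %d codes @ %g Hz, label %s, %d clipped\n",
              length(x$codes), x$rate,
              if (is.null(x$label)) "NA" else x$label, x$n_clipped))
  invisible(x)
}

#' Minimum sampling rate under the Nyquist criterion
#'
#' @param f_signal highest signal frequency in Hz (> 0); for the realized
#'   conditioning chain the 472 Hz upper band edge governs.
#' @return `2 * f_signal` in Hz.
#' @export
#' @examples
#' nyquist_min_rate(472)  # 944 Hz
nyquist_min_rate <- function(f_signal) {
  if (!is.numeric(f_signal) || f_signal <= 0)
    stop("f_signal must be positive", call. = FALSE)
  2 * f_signal
}

#' Conditioning-chain configuration
#'
#' Defaults follow the tuned hardware: pre-amplifier gain 31, final gain 21
#' (total 651), realized cutoffs 471 Hz / 22.7 Hz, 2.5 V offset, 10-bit
#' 0-5 V ADC at 1 kHz. `offset_v = 1.5` reproduces the alternative tuned
#' offset.
#'
#' @param preamp_gain instrumentation-stage gain.
#' @param final_gain non-inverting-stage gain (design range 1-30).
#' @param lp_fc,hp_fc low-/high-pass cutoff frequencies in Hz.
#' @param offset_v offset reference in volts.
#' @param adc_bits,adc_rate ADC resolution and rate.
#' @param filter_method `"analog"` or `"bilinear"`, see [butterworth3()].
#' @return A named list of class `emg_config`.
#' @export
emg_config <- function(preamp_gain = 31, final_gain = 21,
                       lp_fc = 471, hp_fc = 22.7, offset_v = 2.5,
                       adc_bits = 10, adc_rate = 1000,
                       filter_method = "analog") {
  structure(list(preamp_gain = preamp_gain, final_gain = final_gain,
                 lp_fc = lp_fc, hp_fc = hp_fc, offset_v = offset_v,
                 adc_bits = adc_bits, adc_rate = adc_rate,
                 filter_method = filter_method),
            class = "emg_config")
}

#' Run the full conditioning chain
#'
#' Stages in hardware order: pre-amplification, low-pass, high-pass, final
#' amplification, offset, ADC. The electrode signal is treated as the
#' differential input already, so pre-amplification is a pure gain.
#'
#' @param sig an [analog_signal()] (electrode-referred volts).
#' @param config an [emg_config()].
#' @return A `digitized_trial` at `config$adc_rate`.
#' @export
full_chain <- function(sig, config = emg_config()) {
  stopifnot(inherits(sig, "emg_analog"), inherits(config, "emg_config"))
  sig$samples <- config$preamp_gain * sig$samples
  sig <- butterworth3(sig, config$lp_fc, "lowpass", config$filter_method)
  sig <- butterworth3(sig, config$hp_fc, "highpass", config$filter_method)
  sig <- noninverting_gain(sig, r_fb = config$final_gain - 1, r_in = 1)
  sig <- offset_stage(sig, config$offset_v)
  adc_quantize(sig, bits = config$adc_bits, v_min = 0, v_max = 5,
               rate = config$adc_rate)
}
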