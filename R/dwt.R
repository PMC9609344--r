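# Discrete wavelet transform, Daubechies db5 (10 taps), Mallat pyramid with
# half-sample symmetric boundary extension. Conventions follow the common
# filter-bank formulation: per level the signal is extended by L-1 samples
# each side, convolved with the decomposition filters and downsampled to
# floor((n + L - 1) / 2) coefficients; reconstruction upsamples, convolves
# with the time-reversed filters and trims, which is exact (perfect
# reconstruction) for any input length.

# db5 scaling (low-pass decomposition) filter, increasing index.
.db5_dec_lo <- c(
  0.003335725285001549, -0.012580751999015526, -0.006241490213011705,
  0.077571493840065148, -0.032244869585030480, -0.242294887066190480,
  0.138428145901103120, 0.724308528438574370, 0.603829269797472960,
  0.160102397974125030
)

.db5_filters <- function() {
  lo <- .db5_dec_lo
  L <- length(lo)
  hi <- rev(lo) * (-1)^seq_len(L)      # quadrature mirror
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi), L = L)
}

# One analysis step: symmetric extension, valid correlation with the
# reversed filter, downsample by 2.
.dwt_step <- function(x, f) {
  L <- length(f)
  n <- length(x)
  xe <- c(rev(x[seq_len(L - 1)]), x, rev(x[seq(n - L + 2, n)]))
  m <- length(xe) - L + 1
  y <- as.numeric(stats::embed(xe, L) %*% f)   # embed reverses the window
  y[seq(2, m, by = 2)]
}

# One synthesis step: upsample both branches, convolve with reconstruction
# filters, trim L-2 leading samples, keep n.
.idwt_step <- function(a, d, n, filt) {
  up <- function(cf) {
    u <- numeric(2 * length(cf))
    u[seq(1, length(u), by = 2)] <- cf
    u
  }
  y <- stats::convolve(up(a), rev(filt$rec_lo), type = "open") +
    stats::convolve(up(d), rev(filt$rec_hi), type = "open")
  y[(filt$L - 1):(filt$L - 2 + n)]
}

#' Multilevel db5 discrete wavelet transform
#'
#' Five-level (by default) multiresolution analysis with the 10-tap
#' Daubechies db5 wavelet. Each level halves the approximation branch
#' through the scaling/wavelet filter pair; the returned approximation and
#' detail coefficient vectors, together with the recorded lengths, allow
#' exact reconstruction via [idwt_db5()].
#'
#' @param x numeric signal; must be long enough that every level has at
#'   least `L - 1 = 9` input samples.
#' @param levels decomposition depth (default 5).
#' @return list with `approx` and `detail` (lists of coefficient vectors,
#'   level 1 first), `lengths` (input length per level) and `levels`.
#' @export
dwt_db5 <- function(x, levels = 5) {
  filt <- .db5_filters()
  n <- length(x)
  # every level needs at least L - 1 input samples for the extension
  lens <- n
  for (j in seq_len(levels)) lens <- c(lens, floor((lens[j] + filt$L - 1) / 2))
  if (any(lens[seq_len(levels)] < filt$L - 1))
    stop("signal too short for a ", levels, "-level db5 decomposition; ",
         "need at least ", filt$L - 1, " samples at every level", call. = FALSE)
  approx <- detail <- vector("list", levels)
  a <- as.numeric(x)
  for (j in seq_len(levels)) {
    detail[[j]] <- .dwt_step(a, filt$dec_hi)
    a <- .dwt_step(a, filt$dec_lo)
    approx[[j]] <- a
  }
  list(approx = approx, detail = detail,
       lengths = lens[seq_len(levels)], levels = levels)
}

#' Inverse multilevel db5 transform
#'
#' Reconstructs the original signal from a [dwt_db5()] decomposition.
#' Reconstruction is exact to numerical precision (orthogonal filter bank
#' with stored per-level lengths).
#'
#' @param dec a decomposition from [dwt_db5()].
#' @return Numeric vector of the original length.
#' @export
idwt_db5 <- function(dec) {
  filt <- .db5_filters()
  a <- dec$approx[[dec$levels]]
  for (j in rev(seq_len(dec$levels))) {
    a <- .idwt_step(a, dec$detail[[j]], dec$lengths[j], filt)
  }
  a
}
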