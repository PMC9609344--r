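# End-to-end convenience wrapper tying synthesis, conditioning, windowing
# and feature extraction together — the software analogue of one recording
# session with the hardware platform.

#' Run the full acquisition protocol
#'
#' Generates `per_class` synthetic trials per gesture (default protocol:
#' 50 each, 250 total), passes every trial through the conditioning chain
#' and the 10-bit 1 kHz ADC, windows each digitized trial to its 500-sample
#' region of interest and extracts the 20-element feature vector, yielding
#' the 20 x 250 training matrix.
#'
#' @param per_class trials per gesture (default 50).
#' @param seed session seed.
#' @param params optional [synth_params()]; defaults to
#'   `synth_params(seed = seed)`.
#' @param config conditioning-chain [emg_config()].
#' @param width window length in samples (default 500).
#' @return list(features = `feature_dataset`, windows, trials).
#' @export
#' @examples
#' \donttest{
#' run <- run_acquisition_protocol(per_class = 2, seed = 1)
#' dim(run$features$X)  # 20 x 10
#' }
run_acquisition_protocol <- function(per_class = 50, seed = 1,
                                     params = NULL, config = emg_config(),
                                     width = 500) {
  if (is.null(params)) params <- synth_params(seed = seed)
  session <- generate_session(per_class, params)
  trials <- lapply(session, function(s) full_chain(s$signal, config))
  windows <- collect_dataset(trials, per_class = per_class, width = width)
  list(features = batch_extract(windows), windows = windows, trials = trials)
}
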