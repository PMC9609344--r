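# Evaluation: confusion matrices, the 90-random-movement assertiveness
# protocol, and gesture-to-servo command decoding for the five-finger
# prosthesis.

#' Confusion matrix over the five gestures
#'
#' Rows are true classes, columns predicted classes, both 0-4.
#'
#' @param y_true,y_pred equal-length integer label vectors (0-4).
#' @return 5x5 integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length", call. = FALSE)
  if (any(!y_true %in% 0:4) || any(!y_pred %in% 0:4))
    stop("labels must be gesture ids 0-4", call. = FALSE)
  cm <- table(factor(y_true, levels = 0:4), factor(y_pred, levels = 0:4))
  cm <- unclass(as.matrix(cm))
  dimnames(cm) <- list(true = gesture_classes()$name,
                       predicted = gesture_classes()$name)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Accuracy from a confusion matrix
#'
#' @param cm a [confusion_matrix()].
#' @return Percent correct, `100 * trace / total`.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  100 * sum(diag(cm)) / sum(cm)
}

#' The 90-random-movement assertiveness protocol
#'
#' Draws `n` fresh synthetic trials with uniformly random gesture labels,
#' runs each through the complete pipeline (conditioning chain, windowing,
#' feature extraction, classification) and reports the percentage
#' correctly replicated together with the error complement. Seeded and
#' fully reproducible.
#'
#' @param model a trained `mlp_model` with embedded scaler.
#' @param params [synth_params()] template; per-trial seeds are derived
#'   from `seed`.
#' @param n number of random movements (default 90).
#' @param seed protocol seed.
#' @param config conditioning-chain [emg_config()].
#' @return list(assertiveness_pct, error_pct, confusion, labels, predicted).
#' @export
random_trial_protocol <- function(model, params, n = 90, seed = 1,
                                  config = emg_config()) {
  set.seed(as.integer(seed))
  labels <- sample(0:4, n, replace = TRUE)
  preds <- integer(n)
  for (i in seq_len(n)) {
    p <- params
    p$seed <- as.integer((as.numeric(seed) + 7717 * i) %% 2147483647)
    sig <- generate_trial(labels[i], p)
    trial <- full_chain(sig, config)
    w <- window_trial(trial)
    preds[i] <- predict(model, matrix(extract_features(w), nrow = 1))
  }
  cm <- confusion_matrix(labels, preds)
  acc <- accuracy(cm)
  list(assertiveness_pct = acc, error_pct = 100 - acc,
       confusion = cm, labels = labels, predicted = preds)
}

# Fixed class -> five-servo angle map (degrees; 0 extended, 180 flexed),
# channels ordered thumb, index, middle, ring, little. Editable by hardware
# users needing recalibration.
.servo_map <- function() {
  m <- rbind(
    "closed hand" = c(180, 180, 180, 180, 180),
    "grip"        = c(150, 120, 120, 120, 120),
    "index"       = c(0, 180, 0, 0, 0),
    "middle"      = c(0, 0, 180, 0, 0),
    "ring"        = c(0, 0, 0, 180, 0)
  )
  colnames(m) <- c("thumb", "index", "middle", "ring", "little")
  m
}

#' Decode a gesture into servo angles
#'
#' Total, deterministic map from the five gesture classes to the five
#' finger-servo angles (degrees in [0, 180]; 180 = fully flexed). Closed
#' hand flexes every finger; the single-finger gestures flex only their
#' finger; grip is a partial whole-hand flexion.
#'
#' @param label gesture id (0-4) or name.
#' @return Named numeric vector of 5 angles plus a `"gesture"` attribute.
#' @export
#' @examples
#' decode_gesture("index")
decode_gesture <- function(label) {
  id <- gesture_id(label)
  angles <- .servo_map()[id + 1L, ]
  attr(angles, "gesture") <- gesture_name(id)
  angles
}

#' Decode a label stream into servo commands
#'
#' One command per classified window, order preserved and indexed.
#'
#' @param labels vector of gesture ids/names.
#' @return data.frame(step, gesture, thumb, index, middle, ring, little).
#' @export
stream_commands <- function(labels) {
  rows <- lapply(seq_along(labels), function(i) {
    a <- decode_gesture(labels[i])
    data.frame(step = i, gesture = attr(a, "gesture"), t(a))
  })
  do.call(rbind, rows)
}
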