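#' Gesture classes
#'
#' The five hand movements the pipeline classifies: closed hand, grip, and
#' individual index, middle and ring finger movements. Class ids are 0-based
#' and fixed; they double as output-neuron indices in the classifier.
#'
#' @return A data.frame with columns `id` (integer, 0-4) and `name`.
#' @export
#' @examples
#' gesture_classes()
gesture_classes <- function() {
  data.frame(
    id = 0:4,
    name = c("closed hand", "grip", "index", "middle", "ring"),
    stringsAsFactors = FALSE
  )
}

#' Resolve a gesture class to its integer id
#'
#' Accepts an id (0-4) or a class name and returns the validated id.
#'
#' @param cls integer id in 0-4 or one of the five gesture names.
#' @return integer class id.
#' @export
gesture_id <- function(cls) {
  g <- gesture_classes()
  if (is.character(cls)) {
    i <- match(cls, g$name)
    if (is.na(i)) stop("unknown gesture class: '", cls, "'", call. = FALSE)
    return(g$id[i])
  }
  cls <- as.integer(cls)
  if (length(cls) != 1L || is.na(cls) || !cls %in% g$id)
    stop("gesture class id must be an integer in 0-4", call. = FALSE)
  cls
}

gesture_name <- function(id) gesture_classes()$name[id + 1L]
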