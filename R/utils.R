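# Shared constants and small numeric helpers.

.emotions <- c("happiness", "sadness", "anger", "fear", "disgust")
.areas <- c("body_image", "environment_acceptance", "self_esteem")
.stages <- c("I", "II", "III_convalescent", "palliative", "unknown")
.sentiment_classes <- c("negative", "neutral", "positive")

#' Canonical emotion order
#'
#' The five basic emotions scored by the affective lexicon, in the fixed
#' order used everywhere for tie-breaking (argmax ties resolve to the
#' earliest emotion in this order).
#'
#' @return Character vector of length 5.
#' @export
emotions <- function() .emotions

#' Difficulty areas screened by the topic module
#'
#' @return Character vector of the three area identifiers.
#' @export
difficulty_areas <- function() .areas

#' Disease-stage labels
#'
#' Stage labels attached to notes: diagnosis (I), treatment (II),
#' convalescence (III_convalescent), palliative care, or unknown.
#'
#' @return Character vector of stage labels.
#' @export
note_stages <- function() .stages

#' Cosine similarity between two vectors
#'
#' @param x,y Numeric vectors of equal length.
#' @return The cosine of the angle between `x` and `y`, or `NA` when either
#'   vector has zero norm (the angle is undefined).
#' @export
cosine_similarity <- function(x, y) {
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    return(NA_real_)
  }
  sum(x * y) / (nx * ny)
}

# argmax over emotion columns; which.max keeps the first maximum, so ties
# resolve in canonical emotion order.
dominant_from_intensities <- function(m) {
  m <- as.matrix(m)[, .emotions, drop = FALSE]
  .emotions[apply(m, 1L, which.max)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
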