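## scoring: the per-pixel strike score of the current stack.
##
## VIS: a lookup-shifted appearance step at the old/new transition minus
## temporal-variation penalties inside each half, so that a sudden
## persistent change scores high while flicker (moving grass, walkers)
## is punished. LWIR: the difference of the per-half temporal medians,
## which is inherently robust to transient warm objects.

#' Default gray-difference lookup curve for the VIS score
#'
#' Identity through the informative band (carcass-against-vegetation steps
#' are typically 15--30 gray levels), flat at 70 above: large differences
#' are very rarely fatalities and their score is capped so they are not
#' overestimated; the maximal input 255 maps to 70.
#'
#' @return a \linkS4class{ShiftLUT} with anchors (0,0), (70,70), (255,70)
#' @export
defaultShiftLUT <- function() {
  shiftLUT(cbind(c(0, 70, 255), c(0, 70, 70)))
}

#' Construct a ShiftLUT from anchor points
#'
#' @param anchors two-column matrix of (input, output) anchor points;
#'   inputs strictly increasing, covering [0, 255], with output 70 at 255
#' @return a \linkS4class{ShiftLUT}
#' @export
shiftLUT <- function(anchors) {
  new("ShiftLUT", anchors = as.matrix(anchors))
}

#' Evaluate a ShiftLUT at gray differences
#'
#' Piecewise-linear interpolation between the anchor points.
#'
#' @param lut a \linkS4class{ShiftLUT}
#' @param d gray differences in [0, 255] (vector, matrix or scalar)
#' @return the mapped score values, same shape as \code{d}
#' @export
lutShift <- function(lut, d) {
  v <- as.numeric(d)
  ok <- !is.na(v)
  if (any(v[ok] < 0 | v[ok] > 255))
    stop("gray differences must lie in [0, 255]")
  out <- stats::approx(lut@anchors[, 1L], lut@anchors[, 2L], xout = v,
                       rule = 2)$y
  out[!ok] <- NA_real_
  if (is.matrix(d)) out <- matrix(out, nrow(d), ncol(d))
  out
}

#' Construct a ScoringConfig
#'
#' @param channel camera channel the configuration targets
#' @param alpha non-negative weight of the temporal-variation penalties
#'   (VIS only; default 1)
#' @param lut the step-term lookup curve (VIS only)
#' @return a \linkS4class{ScoringConfig}
#' @export
scoringConfig <- function(channel = c("VIS", "LWIR"), alpha = 1.0,
                          lut = defaultShiftLUT()) {
  channel <- match.arg(channel)
  new("ScoringConfig", alpha = as.numeric(alpha), lut = lut,
      channel = channel)
}

#' VIS pixel-wise strike score
#'
#' Per pixel: the lookup-shifted magnitude of the step at the old-to-new
#' transition, minus \code{alpha / (pairs)} times the summed absolute
#' consecutive differences within the new half and within the old half.
#' The transition pair itself is counted only in the step term. A pixel
#' masked in any contributing frame gets a masked (NA) score.
#'
#' @param stack a full, registered, brightness-normalized VIS
#'   \linkS4class{ImageStack}
#' @param config a \linkS4class{ScoringConfig}
#' @return a \linkS4class{ScoreMap}
#' @export
scoreVis <- function(stack, config = scoringConfig("VIS")) {
  if (!identical(channel(stack), "VIS"))
    stop("scoreVis expects a VIS stack")
  halves <- splitHalves(stack)
  old <- lapply(halves$old, function(f) f@pixels)
  new <- lapply(halves$new, function(f) f@pixels)
  nPairsOld <- length(old) - 1L
  nPairsNew <- length(new) - 1L
  if (nPairsOld < 1L || nPairsNew < 1L)
    stop("halfSize too small: penalty terms need at least 2 frames per half")
  step <- abs(new[[1L]] - old[[length(old)]])
  s <- lutShift(config@lut, step)
  pen <- matrix(0, nrow(step), ncol(step))
  for (i in seq_len(nPairsNew)) pen <- pen + abs(new[[i]] - new[[i + 1L]]) / nPairsNew
  for (i in seq_len(nPairsOld)) pen <- pen + abs(old[[i]] - old[[i + 1L]]) / nPairsOld
  s <- s - config@alpha * pen
  mask <- stackMask(stack)
  s[!mask] <- NA_real_
  new("ScoreMap", scores = s, mask = mask, channel = "VIS")
}

#' LWIR pixel-wise strike score
#'
#' Per pixel: the temporal median over the new half minus the temporal
#' median over the old half. The median removes transient warm objects
#' (an animal walking through the scene) from either half.
#'
#' @param stack a full, registered LWIR \linkS4class{ImageStack}
#' @return a \linkS4class{ScoreMap}
#' @export
scoreLwir <- function(stack) {
  if (!identical(channel(stack), "LWIR"))
    stop("scoreLwir expects an LWIR stack")
  halves <- splitHalves(stack)
  medNew <- matrixMedian(lapply(halves$new, function(f) f@pixels))
  medOld <- matrixMedian(lapply(halves$old, function(f) f@pixels))
  s <- medNew - medOld
  mask <- stackMask(stack)
  s[!mask] <- NA_real_
  new("ScoreMap", scores = s, mask = mask, channel = "LWIR")
}

#' Score a stack with the rule of its channel
#'
#' @param stack a full \linkS4class{ImageStack}
#' @param config a \linkS4class{ScoringConfig} (used by the VIS rule)
#' @return a \linkS4class{ScoreMap}
#' @export
scoreStack <- function(stack, config = scoringConfig(channel(stack))) {
  switch(channel(stack),
         VIS = scoreVis(stack, config),
         LWIR = scoreLwir(stack),
         stop("stack has no channel"))
}
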