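## photometry: global brightness compensation between frames.
##
## Clouds passing in front of the sun shift the whole image's brightness
## between two frames taken tens of seconds apart. Matching the median of
## the valid pixels compensates the shift while staying robust to the very
## small outlier region a carcass occupies, and -- unlike histogram
## equalization -- preserves the absolute gray differences the pixel-wise
## score and the region analysis rely on.

#' Additive brightness offset between two frames
#'
#' @param subject,reference \linkS4class{Frame}s of the same shape
#' @return the offset (reference median minus subject median) over the
#'   jointly valid pixels, in gray levels
#' @export
brightnessOffset <- function(subject, reference) {
  valid <- subject@mask & reference@mask
  if (!any(valid)) stop("all pixels masked; cannot estimate brightness")
  stats::median(reference@pixels[valid]) - stats::median(subject@pixels[valid])
}

#' Adjust a frame's median brightness to a reference
#'
#' Shifts the subject so that its valid-pixel median matches the
#' reference's (additively by default), then clips to the 8-bit gray
#' range. The median makes small bright or dark blobs -- potential
#' fatalities -- irrelevant to the estimated offset. The adjustment is
#' idempotent and performed in floating point; quantization is deferred to
#' the end of the scoring chain.
#'
#' @param subject the \linkS4class{Frame} to adjust
#' @param reference the \linkS4class{Frame} whose brightness to match
#' @param method \code{"additive"} (default) or \code{"multiplicative"}
#' @return the adjusted \linkS4class{Frame}
#' @export
adjustMedian <- function(subject, reference,
                         method = c("additive", "multiplicative")) {
  method <- match.arg(method)
  valid <- subject@mask & reference@mask
  if (!any(valid)) stop("all pixels masked; cannot adjust brightness")
  medS <- stats::median(subject@pixels[valid])
  medR <- stats::median(reference@pixels[valid])
  px <- if (method == "additive") {
    subject@pixels + (medR - medS)
  } else {
    if (medS <= 0) stop("subject median is zero; multiplicative adjustment undefined")
    subject@pixels * (medR / medS)
  }
  out <- subject
  out@pixels <- pmin(pmax(px, 0), 255)
  out
}

#' @describeIn normalizeStack Adjust every frame's median to the stack's
#'   reference frame (the newest). The LWIR channel bypasses the
#'   adjustment by default because its gain control is in-camera; pass
#'   \code{force = TRUE} to adjust anyway.
#' @param force adjust even on the LWIR channel
#' @param method see \code{\link{adjustMedian}}
#' @export
setMethod("normalizeStack", "ImageStack",
  function(stack, force = FALSE, method = "additive") {
    if (!isFull(stack)) stop("stack must be full before normalization")
    if (identical(channel(stack), "LWIR") && !force) return(stack)
    ref <- stack@frames[[length(stack@frames)]]
    stack@frames <- lapply(stack@frames, adjustMedian, reference = ref,
                           method = method)
    stack
  })
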