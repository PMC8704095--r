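## decision: preselection and structural-difference criteria.
##
## Preselection is cheap arithmetic on medians (area, temporal and spatial
## discernibility, surround score) meant to discard the bulk of
## implausible candidates; the surviving ones are judged on the structural
## similarity of their full region across consecutive frame pairs: a true
## strike changes the region's structure exactly once, at the middle
## (old-to-new) transition, and nowhere else.

#' Channel-specific preselection thresholds
#'
#' LWIR defaults follow the validated thermal configuration (area 1--100
#' px, temporal and spatial discernibility > 11 gray levels, surround
#' score < 2.9). The VIS channel has no published values; its defaults
#' (area 4--4000 px at the finer ground resolution, same discernibility
#' and surround bounds) are engineering defaults and should be tuned per
#' installation.
#'
#' @param channel \code{"VIS"} or \code{"LWIR"}
#' @param areaMin,areaMax inner-area limits in pixels
#' @param temporalMin,spatialMin discernibility thresholds in gray levels
#' @param surroundMax maximum mean absolute score in the surround annulus
#' @param surroundRadius annulus radius in px; \code{NA} = 3x the full
#'   region's bounding-box diagonal
#' @return a \linkS4class{PreselectionThresholds}
#' @export
preselectionThresholds <- function(channel = c("LWIR", "VIS"),
                                   areaMin = NULL, areaMax = NULL,
                                   temporalMin = 11, spatialMin = 11,
                                   surroundMax = 2.9,
                                   surroundRadius = NA_real_) {
  channel <- match.arg(channel)
  if (is.null(areaMin)) areaMin <- if (channel == "LWIR") 1 else 4
  if (is.null(areaMax)) areaMax <- if (channel == "LWIR") 100 else 4000
  new("PreselectionThresholds", areaMin = as.numeric(areaMin),
      areaMax = as.numeric(areaMax), temporalMin = as.numeric(temporalMin),
      spatialMin = as.numeric(spatialMin),
      surroundMax = as.numeric(surroundMax),
      surroundRadius = as.numeric(surroundRadius))
}

#' Structural decision thresholds
#'
#' @param middleSdiffMin minimum SDIFF of the middle frame pair
#' @param sideSdiffMax maximum SDIFF allowed in any side pair
#' @param sdiffQuotientMin minimum middle / max(side) quotient
#' @param c1,c2 SSIM stabilizers on the normalized gray scale; c2 = 0.03
#'   keeps near-constant patches from being dominated by sensor noise
#' @return a \linkS4class{StructuralThresholds}
#' @export
structuralThresholds <- function(middleSdiffMin = 0.005, sideSdiffMax = 0.05,
                                 sdiffQuotientMin = 3.0, c1 = 1e-4,
                                 c2 = 0.03) {
  new("StructuralThresholds", middleSdiffMin = as.numeric(middleSdiffMin),
      sideSdiffMax = as.numeric(sideSdiffMax),
      sdiffQuotientMin = as.numeric(sdiffQuotientMin),
      c1 = as.numeric(c1), c2 = as.numeric(c2))
}

## pooled gray values of a pixel set over a list of frames, honoring masks
.poolValues <- function(frames, coords, dim) {
  idx <- coordsToIndex(coords, dim)
  unlist(lapply(frames, function(f) f@pixels[idx][f@mask[idx]]))
}

#' Preselection of a candidate region
#'
#' Computes the four cheap criteria: (1) inner area within limits; (2)
#' temporal discernibility, median of the inner pixels over the new
#' frames minus median of the full pixels over the old frames; (3)
#' spatial discernibility, median of the inner pixels minus median of the
#' outer pixels, both over the new frames; (4) the mean absolute score in
#' the annulus within \code{surroundRadius} of the full region, excluding
#' the region itself, which rejects wind gusts that elevate scores over a
#' large area. On LWIR the victim is assumed warmer than its surround
#' (differences as written); on VIS it is assumed darker (differences
#' sign-flipped).
#'
#' @param region one region record from a \linkS4class{RegionSet}
#' @param stack the full (normalized) \linkS4class{ImageStack}
#' @param score the stack's \linkS4class{ScoreMap}
#' @param thresholds a \linkS4class{PreselectionThresholds}
#' @return list with \code{values} (named criterion values), \code{pass}
#'   (logical) and \code{reason} (first failing criterion or \code{""})
#' @export
preselect <- function(region, stack, score,
                      thresholds = preselectionThresholds(channel(stack))) {
  dm <- dim(score@scores)
  halves <- splitHalves(stack)
  sgn <- if (identical(channel(stack), "VIS")) -1 else 1
  area <- region$area
  newInner <- .poolValues(halves$new, region$inner, dm)
  oldFull <- .poolValues(halves$old, region$full, dm)
  temporal <- sgn * (stats::median(newInner) - stats::median(oldFull))
  if (nrow(region$outer) == 0L) {
    values <- list(area = area, temporal = temporal, spatial = NA_real_,
                   surround = NA_real_)
    return(list(values = values, pass = FALSE,
                reason = "spatial discernibility incomputable: empty outer set"))
  }
  newOuter <- .poolValues(halves$new, region$outer, dm)
  spatial <- sgn * (stats::median(newInner) - stats::median(newOuter))
  ## surround annulus around the full region
  radius <- thresholds@surroundRadius
  if (is.na(radius)) {
    dh <- region$bbox[2L] - region$bbox[1L] + 1L
    dw <- region$bbox[4L] - region$bbox[3L] + 1L
    radius <- ceiling(3 * sqrt(dh^2 + dw^2))
  }
  fullMask <- matrix(FALSE, dm[1L], dm[2L])
  fullMask[coordsToIndex(region$full, dm)] <- TRUE
  annulus <- dilateMask(fullMask, radius) & !fullMask & score@mask
  surround <- if (any(annulus)) mean(abs(score@scores[annulus])) else 0
  values <- list(area = area, temporal = temporal, spatial = spatial,
                 surround = surround)
  if (area < thresholds@areaMin || area > thresholds@areaMax)
    return(list(values = values, pass = FALSE, reason = "area"))
  if (!(temporal > thresholds@temporalMin))
    return(list(values = values, pass = FALSE,
                reason = "temporal discernibility"))
  if (!(spatial > thresholds@spatialMin))
    return(list(values = values, pass = FALSE,
                reason = "spatial discernibility"))
  if (!(surround < thresholds@surroundMax))
    return(list(values = values, pass = FALSE, reason = "surround score"))
  list(values = values, pass = TRUE, reason = "")
}

#' Structural similarity of two gray-value vectors
#'
#' The statistics-only similarity of two pixel vectors (means, population
#' variances and covariance), computed over the (possibly non-square)
#' pixel set of one full region at two consecutive time steps. Inputs are
#' expected on the normalized [0, 1] gray scale so that the stabilizers
#' keep their meaning at any bit depth.
#'
#' @param x,y numeric vectors of equal length >= 2
#' @param c1,c2 stabilizers guarding the mean and variance terms against
#'   zero denominators
#' @return the similarity value (1 = total similarity)
#' @export
ssim <- function(x, y, c1 = 1e-4, c2 = 0.03) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("ssim needs at least 2 pixels")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2)
  vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Structural-difference series of a region across the stack
#'
#' One SDIFF = 1 - SSIM per consecutive frame pair (2N - 1 values for a
#' 2N-frame stack), computed over the region's full pixel set on the
#' normalized gray scale and clipped into [0, 1]. A region whose full set
#' is more than \code{maxMaskedFraction} masked in any frame is refused.
#'
#' @param region one region record from a \linkS4class{RegionSet}
#' @param stack the full \linkS4class{ImageStack}
#' @param thresholds a \linkS4class{StructuralThresholds} (supplies c1, c2)
#' @param maxMaskedFraction maximum tolerated masked fraction
#' @return numeric vector of SDIFF values in [0, 1]
#' @export
sdiffSeries <- function(region, stack, thresholds = structuralThresholds(),
                        maxMaskedFraction = 0.2) {
  fs <- stack@frames
  dm <- dim(fs[[1L]]@pixels)
  idx <- coordsToIndex(region$full, dm)
  maskedFrac <- vapply(fs, function(f) mean(!f@mask[idx]), numeric(1))
  if (any(maskedFrac > maxMaskedFraction))
    stop(sprintf("region masked fraction %.2f exceeds %.2f",
                 max(maskedFrac), maxMaskedFraction))
  out <- numeric(length(fs) - 1L)
  for (i in seq_len(length(fs) - 1L)) {
    ok <- fs[[i]]@mask[idx] & fs[[i + 1L]]@mask[idx]
    x <- fs[[i]]@pixels[idx][ok] / 255
    y <- fs[[i + 1L]]@pixels[idx][ok] / 255
    out[i] <- 1 - ssim(x, y, thresholds@c1, thresholds@c2)
  }
  pmin(pmax(out, 0), 1)
}

#' Structural decision on an SDIFF series
#'
#' Detected iff the middle pair's SDIFF exceeds \code{middleSdiffMin}, no
#' side pair exceeds \code{sideSdiffMax}, and the quotient middle /
#' max(side) exceeds \code{sdiffQuotientMin} (all side SDIFFs zero counts
#' as an infinite quotient). The rejection reason names the first failing
#' criterion.
#'
#' @param sdiffs odd-length SDIFF series with the strike transition at the
#'   middle position
#' @param thresholds a \linkS4class{StructuralThresholds}
#' @return list with \code{verdict} (\code{"detected"} or
#'   \code{"rejected_structural"}), \code{reason} and \code{values}
#' @export
structuralDecision <- function(sdiffs, thresholds = structuralThresholds()) {
  n <- length(sdiffs)
  if (n < 3L || n %% 2L == 0L)
    stop("sdiffs must have odd length >= 3 with a well-defined middle pair")
  mid <- (n + 1L) %/% 2L
  middle <- sdiffs[mid]
  maxSide <- max(sdiffs[-mid])
  quotient <- if (maxSide == 0) Inf else middle / maxSide
  values <- list(middleSdiff = middle, maxSideSdiff = maxSide,
                 sdiffQuotient = quotient)
  if (!(middle > thresholds@middleSdiffMin))
    return(list(verdict = "rejected_structural",
                reason = "middle SDIFF", values = values))
  if (!(maxSide < thresholds@sideSdiffMax))
    return(list(verdict = "rejected_structural",
                reason = "side SDIFF", values = values))
  if (!(quotient > thresholds@sdiffQuotientMin))
    return(list(verdict = "rejected_structural",
                reason = "SDIFF quotient", values = values))
  list(verdict = "detected", reason = "", values = values)
}

#' Full evaluation of one candidate region
#'
#' Runs preselection, then -- only for survivors -- the structural
#' SDIFF analysis, and records every computed criterion value.
#'
#' @param region one region record from a \linkS4class{RegionSet}
#' @param stack the full (normalized) \linkS4class{ImageStack}
#' @param score the stack's \linkS4class{ScoreMap}
#' @param preThresholds a \linkS4class{PreselectionThresholds}
#' @param structThresholds a \linkS4class{StructuralThresholds}
#' @param maxMaskedFraction regions more masked than this are rejected
#' @return a \linkS4class{CandidateEvaluation}
#' @export
evaluateCandidate <- function(region, stack, score,
                              preThresholds =
                                preselectionThresholds(channel(stack)),
                              structThresholds = structuralThresholds(),
                              maxMaskedFraction = 0.2) {
  pre <- preselect(region, stack, score, preThresholds)
  if (!pre$pass)
    return(new("CandidateEvaluation", region = region,
               criterionValues = pre$values, sdiffSeries = numeric(0),
               verdict = "rejected_preselection",
               rejectionReason = pre$reason))
  sd <- tryCatch(
    sdiffSeries(region, stack, structThresholds, maxMaskedFraction),
    error = function(e) NULL)
  if (is.null(sd))
    return(new("CandidateEvaluation", region = region,
               criterionValues = pre$values, sdiffSeries = numeric(0),
               verdict = "rejected_structural",
               rejectionReason = "region too masked for structural analysis"))
  dec <- structuralDecision(sd, structThresholds)
  new("CandidateEvaluation", region = region,
      criterionValues = c(pre$values, dec$values), sdiffSeries = sd,
      verdict = dec$verdict, rejectionReason = dec$reason)
}
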