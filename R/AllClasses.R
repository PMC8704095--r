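#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core containers
## ---------------------------------------------------------------------------

#' Frame: one registered grayscale camera image
#'
#' A single-channel grayscale image with acquisition timestamp and channel
#' tag. Pixels are stored as a numeric matrix on the 8-bit gray scale
#' (0--255); fractional values are permitted so that photometric
#' adjustments and interpolation do not accumulate quantization error. The
#' logical \code{mask} marks valid pixels; pixels that left the field of
#' view during registration are masked and ignored by every downstream
#' statistic.
#'
#' @slot pixels numeric matrix of gray values in [0, 255]
#' @slot timestamp seconds since epoch
#' @slot channel either \code{"VIS"} or \code{"LWIR"}
#' @slot frameId monotone integer identifier within a sequence
#' @slot mask logical matrix, \code{TRUE} where the pixel is valid
#' @exportClass Frame
setClass("Frame",
  representation(
    pixels = "matrix",
    timestamp = "numeric",
    channel = "character",
    frameId = "integer",
    mask = "matrix"
  )
)

setValidity("Frame", function(object) {
  p <- object@pixels
  if (!is.numeric(p) || length(p) == 0L)
    return("pixels must be a non-empty numeric matrix")
  v <- p[object@mask]
  if (length(v) && (min(v) < -1e-9 || max(v) > 255 + 1e-9))
    return("valid pixel values must lie in [0, 255]")
  if (!identical(dim(object@mask), dim(p)))
    return("mask must have the same shape as pixels")
  if (!is.logical(object@mask))
    return("mask must be logical")
  if (!object@channel %in% c("VIS", "LWIR"))
    return("channel must be 'VIS' or 'LWIR'")
  if (length(object@timestamp) != 1L || !is.finite(object@timestamp))
    return("timestamp must be a single finite number")
  TRUE
})

#' Construct a Frame
#'
#' @param pixels numeric matrix of gray values in [0, 255]
#' @param timestamp acquisition time in seconds since epoch
#' @param channel \code{"VIS"} (visible/near-infrared) or \code{"LWIR"}
#'   (thermal)
#' @param frameId integer identifier; defaults to 0
#' @param mask optional logical validity matrix (default: all valid)
#' @return a \linkS4class{Frame}
#' @export
Frame <- function(pixels, timestamp, channel = c("VIS", "LWIR"),
                  frameId = 0L, mask = NULL) {
  channel <- match.arg(channel)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  new("Frame", pixels = pixels, timestamp = as.numeric(timestamp),
      channel = channel, frameId = as.integer(frameId), mask = mask)
}

#' ImageStack: FIFO temporal window of 2N frames
#'
#' The rolling window the detector evaluates: the older N frames are the
#' \emph{old} half, the newer N the \emph{new} half. A collision victim is
#' modelled as an object present in every new frame and in none of the old
#' ones. The stack accepts frames via \code{\link{pushFrame}} and evicts
#' the oldest once \code{2 * halfSize} frames are held.
#'
#' @slot frames list of \linkS4class{Frame}, oldest first
#' @slot halfSize N, the number of frames per half (>= 2)
#' @slot excludeMiddle if \code{TRUE} the innermost frame of each half is
#'   omitted from scoring, guarding against catching the falling object
#'   mid-air in the transition frame
#' @slot frameInterval nominal seconds between frames (metadata; scoring is
#'   index-based)
#' @exportClass ImageStack
setClass("ImageStack",
  representation(
    frames = "list",
    halfSize = "integer",
    excludeMiddle = "logical",
    frameInterval = "numeric"
  )
)

setValidity("ImageStack", function(object) {
  if (object@halfSize < 2L) return("halfSize must be >= 2")
  if (length(object@frames) > 2L * object@halfSize)
    return("stack cannot hold more than 2*halfSize frames")
  if (length(object@frames) >= 2L) {
    ts <- vapply(object@frames, function(f) f@timestamp, numeric(1))
    if (any(diff(ts) <= 0)) return("timestamps must be strictly increasing")
    ch <- vapply(object@frames, function(f) f@channel, character(1))
    if (length(unique(ch)) != 1L) return("all frames must share one channel")
    d <- dim(object@frames[[1L]]@pixels)
    ok <- vapply(object@frames, function(f) identical(dim(f@pixels), d),
                 logical(1))
    if (!all(ok)) return("all frames must share one shape")
  }
  TRUE
})

#' Construct an empty ImageStack
#'
#' @param halfSize frames per half (N >= 2); default 5 gives the canonical
#'   10-frame window
#' @param excludeMiddle drop the innermost frame of each half from scoring
#' @param frameInterval nominal seconds between frames (default 10 s)
#' @return an empty \linkS4class{ImageStack}
#' @export
ImageStack <- function(halfSize = 5L, excludeMiddle = FALSE,
                       frameInterval = 10) {
  new("ImageStack", frames = list(), halfSize = as.integer(halfSize),
      excludeMiddle = excludeMiddle, frameInterval = as.numeric(frameInterval))
}

#' AffineTransform: mapping from moving-frame to reference-frame coordinates
#'
#' @slot coefficients 2x3 matrix A such that (x', y')^T = A (x, y, 1)^T in
#'   (col, row) pixel coordinates
#' @slot nInliers number of consensus keypoint matches behind the estimate
#' @slot residual median alignment residual of the inliers, in pixels
#' @exportClass AffineTransform
setClass("AffineTransform",
  representation(coefficients = "matrix", nInliers = "integer",
                 residual = "numeric")
)

setValidity("AffineTransform", function(object) {
  a <- object@coefficients
  if (!identical(dim(a), c(2L, 3L))) return("coefficients must be 2x3")
  if (abs(det(a[, 1:2])) < 1e-12) return("linear part must be non-singular")
  TRUE
})

#' ScoreMap: per-pixel strike score for one stack evaluation
#'
#' @slot scores numeric matrix aligned with the frames; \code{NA} where masked
#' @slot mask logical validity matrix (a pixel is valid only if valid in
#'   every contributing frame)
#' @slot channel the channel the score rule belongs to
#' @exportClass ScoreMap
setClass("ScoreMap",
  representation(scores = "matrix", mask = "matrix", channel = "character")
)

#' RegionSet: labeled candidate regions from one stack evaluation
#'
#' Each region carries three pixel sets: \code{inner} (the putative strike
#' victim: the pixels that survived thresholding), \code{outer} (its
#' surrounding annulus) and \code{full} (the 8-connected dilated component
#' containing both, including the separating gap). The construction
#' guarantees equal numbers of inner, outer and full sets.
#'
#' @slot regions list; each element has fields \code{label}, \code{inner},
#'   \code{outer}, \code{full} ((row, col) integer matrices),
#'   \code{centroid}, \code{area}, \code{bbox}
#' @slot dim image dimensions (rows, cols)
#' @exportClass RegionSet
setClass("RegionSet", representation(regions = "list", dim = "integer"))

setValidity("RegionSet", function(object) {
  for (rg in object@regions) {
    need <- c("label", "inner", "outer", "full", "centroid", "area")
    if (!all(need %in% names(rg))) return("region is missing fields")
    if (nrow(rg$inner) == 0L) return("inner set must be non-empty")
    ii <- coordsToIndex(rg$inner, object@dim)
    oi <- coordsToIndex(rg$outer, object@dim)
    fi <- coordsToIndex(rg$full, object@dim)
    if (length(intersect(ii, oi))) return("inner and outer must be disjoint")
    if (!all(ii %in% fi) || !all(oi %in% fi))
      return("inner and outer must be subsets of full")
  }
  labs <- vapply(object@regions, function(r) r$label, numeric(1))
  if (anyDuplicated(labs)) return("labels must be unique")
  TRUE
})

#' DetectionEvent: an accepted collision-fatality candidate
#'
#' @slot timestamp time of the first new-half frame (the assumed strike time)
#' @slot centroid (row, col) of the candidate's inner pixels, 1-based
#' @slot area inner pixel count
#' @slot channel camera channel
#' @slot frameIds ids of the frames in the deciding stack
#' @slot criteria named list of every criterion value computed for the
#'   candidate, with the thresholds in force
#' @slot sdiffs the per-consecutive-pair structural-difference series
#' @exportClass DetectionEvent
setClass("DetectionEvent",
  representation(
    timestamp = "numeric", centroid = "numeric", area = "integer",
    channel = "character", frameIds = "integer", criteria = "list",
    sdiffs = "numeric"
  )
)

## ---------------------------------------------------------------------------
## Configuration records
## ---------------------------------------------------------------------------

#' ShiftLUT: piecewise-linear remapping of gray differences to scores
#'
#' The visible-channel step score passes the per-pixel gray difference
#' through a lookup curve that keeps the informative range (differences of
#' roughly 15--30 gray levels, typical of a carcass appearing against
#' bright vegetation) unchanged while compressing large differences, which
#' are rarely fatalities: the maximal input 255 maps to 70.
#'
#' @slot anchors two-column matrix (input, output); inputs strictly
#'   increasing and covering [0, 255]
#' @exportClass ShiftLUT
setClass("ShiftLUT", representation(anchors = "matrix"))

setValidity("ShiftLUT", function(object) {
  a <- object@anchors
  if (ncol(a) != 2L || nrow(a) < 2L) return("anchors must be an n x 2 matrix")
  if (any(diff(a[, 1L]) <= 0)) return("anchor inputs must strictly increase")
  if (a[1L, 1L] != 0 || a[nrow(a), 1L] != 255)
    return("anchors must cover [0, 255]")
  if (a[nrow(a), 2L] != 70)
    return("the output at input 255 must be 70")
  TRUE
})

#' ScoringConfig: parameters of the pixel-wise strike score
#'
#' @slot alpha non-negative weight of the temporal-variation penalty terms
#' @slot lut the \linkS4class{ShiftLUT} applied to the step term (VIS)
#' @slot channel channel the configuration is meant for
#' @exportClass ScoringConfig
setClass("ScoringConfig",
  representation(alpha = "numeric", lut = "ShiftLUT", channel = "character")
)

setValidity("ScoringConfig", function(object) {
  if (object@alpha < 0) return("alpha must be >= 0")
  TRUE
})

#' PreselectionThresholds: the cheap candidate filters
#'
#' Area limits on the inner pixel count, minimum temporal and spatial
#' discernibility in gray levels, and the maximum mean absolute score
#' allowed in the surround annulus (the wind-gust rejection). A
#' \code{surroundRadius} of \code{NA} means automatic: three times the full
#' region's bounding-box diagonal.
#'
#' @slot areaMin,areaMax inner-area limits in pixels
#' @slot temporalMin minimum median(new, inner) - median(old, full)
#' @slot spatialMin minimum median(new, inner) - median(new, outer)
#' @slot surroundMax maximum mean |score| in the surround annulus
#' @slot surroundRadius Chebyshev radius of the annulus in pixels, or NA
#' @exportClass PreselectionThresholds
setClass("PreselectionThresholds",
  representation(areaMin = "numeric", areaMax = "numeric",
                 temporalMin = "numeric", spatialMin = "numeric",
                 surroundMax = "numeric", surroundRadius = "numeric")
)

setValidity("PreselectionThresholds", function(object) {
  if (object@areaMin > object@areaMax) return("areaMin must be <= areaMax")
  TRUE
})

#' StructuralThresholds: the SSIM/SDIFF decision parameters
#'
#' @slot middleSdiffMin minimum structural difference of the middle frame
#'   pair (the assumed strike transition)
#' @slot sideSdiffMax maximum structural difference allowed in any other
#'   pair (a still carcass changes nothing elsewhere)
#' @slot sdiffQuotientMin minimum ratio middle / max(side)
#' @slot c1,c2 SSIM stabilizers on the normalized [0, 1] gray scale
#' @exportClass StructuralThresholds
setClass("StructuralThresholds",
  representation(middleSdiffMin = "numeric", sideSdiffMax = "numeric",
                 sdiffQuotientMin = "numeric", c1 = "numeric", c2 = "numeric")
)

setValidity("StructuralThresholds", function(object) {
  vals <- c(object@middleSdiffMin, object@sideSdiffMax,
            object@sdiffQuotientMin, object@c1, object@c2)
  if (any(vals <= 0)) return("all structural thresholds must be positive")
  TRUE
})

#' CandidateEvaluation: full criteria record for one candidate region
#'
#' @slot region the evaluated region (list as held by a
#'   \linkS4class{RegionSet})
#' @slot criterionValues named list of computed criterion values
#' @slot sdiffSeries per-consecutive-pair SDIFF values (empty if the
#'   candidate fell at preselection)
#' @slot verdict one of \code{"rejected_preselection"},
#'   \code{"rejected_structural"}, \code{"detected"}
#' @slot rejectionReason the first failing criterion, or \code{""}
#' @exportClass CandidateEvaluation
setClass("CandidateEvaluation",
  representation(region = "list", criterionValues = "list",
                 sdiffSeries = "numeric", verdict = "character",
                 rejectionReason = "character")
)

setValidity("CandidateEvaluation", function(object) {
  if (!object@verdict %in%
      c("rejected_preselection", "rejected_structural", "detected"))
    return("unknown verdict")
  TRUE
})

#' DetectorConfig: everything the end-to-end detector needs
#'
#' Built by \code{\link{detectorConfig}}, which resolves channel-specific
#' defaults (LWIR skips morphological opening so single-pixel targets
#' survive; LWIR skips brightness normalization because its gain control is
#' in-camera).
#'
#' @slot channel camera channel
#' @slot halfSize,excludeMiddle,frameInterval stack parameters
#' @slot register run frame registration (disable for pre-aligned input)
#' @slot minKeypoints,searchRadius,patchRadius registration parameters
#' @slot normalizeBrightness apply median brightness adjustment per stack
#' @slot scoring \linkS4class{ScoringConfig}
#' @slot blockSize,thresholdOffset adaptive-threshold parameters
#' @slot openingRadius,dilateIters,gapIters region-generation morphology
#' @slot preselection \linkS4class{PreselectionThresholds}
#' @slot structural \linkS4class{StructuralThresholds}
#' @slot maxMaskedFraction discard regions more masked than this
#' @slot dedupWindow suppress re-detections within this many stack positions
#' @slot seed integer seed for the stochastic registration fit
#' @exportClass DetectorConfig
setClass("DetectorConfig",
  representation(
    channel = "character", halfSize = "integer", excludeMiddle = "logical",
    frameInterval = "numeric", register = "logical", minKeypoints = "integer",
    searchRadius = "integer", patchRadius = "integer",
    normalizeBrightness = "logical", scoring = "ScoringConfig",
    blockSize = "integer", thresholdOffset = "numeric",
    openingRadius = "integer", dilateIters = "integer", gapIters = "integer",
    preselection = "PreselectionThresholds",
    structural = "StructuralThresholds", maxMaskedFraction = "numeric",
    dedupWindow = "integer", seed = "integer"
  )
)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "Frame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Frame %d [%s] %dx%d, t=%.1f, %.1f%% valid\n",
              object@frameId, object@channel, d[1L], d[2L],
              object@timestamp, 100 * mean(object@mask)))
})

setMethod("show", "ImageStack", function(object) {
  cat(sprintf("ImageStack: %d/%d frames (N=%d%s, dt=%gs)\n",
              length(object@frames), 2L * object@halfSize, object@halfSize,
              if (object@excludeMiddle) ", middle excluded" else "",
              object@frameInterval))
})

setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform (moving -> reference):\n")
  print(round(object@coefficients, 4))
  cat(sprintf("  inliers: %d, median residual: %.3f px\n",
              object@nInliers, object@residual))
})

setMethod("show", "ScoreMap", function(object) {
  v <- object@scores[object@mask]
  cat(sprintf("ScoreMap [%s] %dx%d, range [%.2f, %.2f]\n", object@channel,
              nrow(object@scores), ncol(object@scores),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet: %d candidate region(s) on a %dx%d map\n",
              length(object@regions), object@dim[1L], object@dim[2L]))
})

setMethod("show", "DetectionEvent", function(object) {
  cat(sprintf(
    "DetectionEvent [%s] t=%.1f at (%.1f, %.1f), area %d px\n",
    object@channel, object@timestamp, object@centroid[1L],
    object@centroid[2L], object@area))
})

setMethod("show", "CandidateEvaluation", function(object) {
  cat(sprintf("CandidateEvaluation: %s%s\n", object@verdict,
              if (nzchar(object@rejectionReason))
                paste0(" (", object@rejectionReason, ")") else ""))
})
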