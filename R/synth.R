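## synth: ground-truthed synthetic monitoring scenes.
##
## The generator renders the disturbance modes the detector must survive:
## a textured vegetation background (smoothed noise, keypoint-rich for
## registration), global illumination steps (clouds), wind-driven
## spatially coherent gray-value fluctuation, transient walkers, briefly
## dwelling sitters, and the signal itself -- a sudden persistent small
## object, darkening on VIS and warming with exponential cooling on LWIR.

#' SceneSpec: parameters of one synthetic monitoring sequence
#'
#' @slot width,height image size in pixels
#' @slot nFrames,frameInterval sequence length and frame spacing (s)
#' @slot channel \code{"VIS"} or \code{"LWIR"}; objects darken the VIS
#'   background and warm the LWIR background
#' @slot baseGray,textureAmplitude,correlationLength background model:
#'   base level plus smoothed-noise texture of the given amplitude (gray
#'   levels) and spatial correlation length (px)
#' @slot noiseSigma per-pixel, per-frame sensor noise sd in gray levels
#' @slot illuminationEvents data.frame(frame, offset): persistent global
#'   brightness steps
#' @slot windEvents data.frame(startFrame, endFrame, row, col, radius,
#'   amplitude): zero-mean coherent fluctuation over a disc
#' @slot walkerEvents data.frame(startFrame, endFrame, startRow, startCol,
#'   endRow, endCol, size, contrast): an animal crossing the scene
#' @slot sitterEvents data.frame(startFrame, dwell, row, col, size,
#'   contrast, jitter): an animal dwelling with small positional jitter
#' @slot dropEvents data.frame(frame, row, col, size, contrast, tau): the
#'   sudden persistent object; on LWIR its contrast decays with time
#'   constant tau (s)
#' @slot jitterSigmaPx,jitterSigmaDeg per-frame nacelle motion (sd of
#'   translation in px and rotation in degrees)
#' @slot seed integer; same spec + seed gives bit-identical frames
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(
    width = "integer", height = "integer", nFrames = "integer",
    frameInterval = "numeric", channel = "character", baseGray = "numeric",
    textureAmplitude = "numeric", correlationLength = "numeric",
    noiseSigma = "numeric", illuminationEvents = "data.frame",
    windEvents = "data.frame", walkerEvents = "data.frame",
    sitterEvents = "data.frame", dropEvents = "data.frame",
    jitterSigmaPx = "numeric", jitterSigmaDeg = "numeric", seed = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  n <- object@nFrames
  inRange <- function(f) all(f >= 1 & f <= n)
  if (nrow(object@illuminationEvents) &&
      !inRange(object@illuminationEvents$frame))
    return("illumination event frames outside the sequence")
  if (nrow(object@windEvents) &&
      !(inRange(object@windEvents$startFrame) &&
        inRange(object@windEvents$endFrame)))
    return("wind event frames outside the sequence")
  if (nrow(object@dropEvents)) {
    d <- object@dropEvents
    if (!inRange(d$frame)) return("drop event frames outside the sequence")
    if (any(d$size < 1)) return("drop footprints must be >= 1 px")
    fp <- lapply(seq_len(nrow(d)), function(i) {
      cc <- footprintCoords(d$row[i], d$col[i], d$size[i])
      if (any(cc[, 1L] < 1 | cc[, 1L] > object@height |
              cc[, 2L] < 1 | cc[, 2L] > object@width))
        return(NULL)
      coordsToIndex(cc, c(object@height, object@width))
    })
    if (any(vapply(fp, is.null, logical(1))))
      return("drop footprint outside the image")
    if (nrow(d) > 1L && any(duplicated(unlist(fp))))
      return("overlapping drop footprints: ground truth would be ambiguous")
  }
  TRUE
})

.emptyEvents <- function(cols) {
  df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                      cols))
  df
}

#' Construct a SceneSpec
#'
#' Defaults describe the nighttime (thermal) study condition: a 64x64
#' frame at 10 s spacing, vegetation-textured background and one gray
#' level of sensor noise (thermal sensor noise is far below one 8-bit
#' gray level at the contrasts of interest, so quantization dominates
#' the pixel-level fluctuation). Event tables default to empty; see
#' \linkS4class{SceneSpec} for their columns.
#'
#' @param width,height,nFrames,frameInterval,channel,baseGray see
#'   \linkS4class{SceneSpec}
#' @param textureAmplitude,correlationLength,noiseSigma background model
#' @param illuminationEvents,windEvents,walkerEvents,sitterEvents,dropEvents
#'   event tables
#' @param jitterSigmaPx,jitterSigmaDeg per-frame nacelle motion
#' @param seed integer seed
#' @return a \linkS4class{SceneSpec}
#' @export
sceneSpec <- function(width = 64L, height = 64L, nFrames = 40L,
                      frameInterval = 10, channel = c("LWIR", "VIS"),
                      baseGray = 100, textureAmplitude = 12,
                      correlationLength = 2, noiseSigma = 1,
                      illuminationEvents = NULL, windEvents = NULL,
                      walkerEvents = NULL, sitterEvents = NULL,
                      dropEvents = NULL, jitterSigmaPx = 0,
                      jitterSigmaDeg = 0, seed = 1L) {
  channel <- match.arg(channel)
  if (is.null(illuminationEvents))
    illuminationEvents <- .emptyEvents(c("frame", "offset"))
  if (is.null(windEvents))
    windEvents <- .emptyEvents(c("startFrame", "endFrame", "row", "col",
                                 "radius", "amplitude"))
  if (is.null(walkerEvents))
    walkerEvents <- .emptyEvents(c("startFrame", "endFrame", "startRow",
                                   "startCol", "endRow", "endCol", "size",
                                   "contrast"))
  if (is.null(sitterEvents))
    sitterEvents <- .emptyEvents(c("startFrame", "dwell", "row", "col",
                                   "size", "contrast", "jitter"))
  if (is.null(dropEvents))
    dropEvents <- .emptyEvents(c("frame", "row", "col", "size", "contrast",
                                 "tau"))
  new("SceneSpec", width = as.integer(width), height = as.integer(height),
      nFrames = as.integer(nFrames), frameInterval = as.numeric(frameInterval),
      channel = channel, baseGray = as.numeric(baseGray),
      textureAmplitude = as.numeric(textureAmplitude),
      correlationLength = as.numeric(correlationLength),
      noiseSigma = as.numeric(noiseSigma),
      illuminationEvents = illuminationEvents, windEvents = windEvents,
      walkerEvents = walkerEvents, sitterEvents = sitterEvents,
      dropEvents = dropEvents, jitterSigmaPx = as.numeric(jitterSigmaPx),
      jitterSigmaDeg = as.numeric(jitterSigmaDeg), seed = as.integer(seed))
}

#' Exponential cooling of a dropped warm object
#'
#' Newton-like cooling of the thermal contrast between a freshly dropped
#' warm body and its surround: \code{delta0 * exp(-t / tau)}. With the
#' default time constant of 300 s a body-temperature phantom keeps a
#' detectable contrast for well over five minutes.
#'
#' @param delta0 initial contrast (gray levels or kelvin-equivalent)
#' @param tau cooling time constant in seconds (> 0)
#' @param t seconds since the drop (>= 0)
#' @return the remaining contrast
#' @export
coolingCurve <- function(delta0, tau, t) {
  if (any(tau <= 0)) stop("tau must be positive")
  if (any(t < 0)) stop("t must be non-negative")
  delta0 * exp(-t / tau)
}

## Deterministic pixel footprint of a given size around (row, col):
## offsets ordered by Chebyshev ring, then row, then col.
footprintCoords <- function(row, col, size) {
  r <- 2L
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[order(pmax(abs(off$dr), abs(off$dc)), off$dr, off$dc), ]
  off <- off[seq_len(size), , drop = FALSE]
  cbind(row + off$dr, col + off$dc)
}

## smoothed unit-variance noise field
.smoothNoise <- function(h, w, corrLen) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (corrLen > 0) {
    z <- EBImage::gblur(z, sigma = corrLen)
    z <- z / stats::sd(z)
  }
  z
}

#' Render a synthetic monitoring sequence with ground truth
#'
#' Frames are rendered as background + illumination steps + wind
#' fluctuation + walkers/sitters + drops (persisting to the end of the
#' sequence, cooling on LWIR), then warped by the per-frame nacelle
#' motion, degraded by sensor noise and quantized to 8 bits.
#'
#' @param spec a \linkS4class{SceneSpec}
#' @return list with \code{frames} (list of \linkS4class{Frame}),
#'   \code{truth} (data.frame: type, frame, time, row, col, size) and
#'   \code{transforms} (per-frame true frame-to-reference
#'   \linkS4class{AffineTransform}s, or NULL without nacelle motion)
#' @export
generateSequence <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  h <- spec@height; w <- spec@width
  n <- spec@nFrames; dt <- spec@frameInterval
  sgn <- if (spec@channel == "LWIR") 1 else -1
  background <- spec@baseGray +
    spec@textureAmplitude * .smoothNoise(h, w, spec@correlationLength)
  ## precompute wind disc masks
  windMasks <- lapply(seq_len(nrow(spec@windEvents)), function(i) {
    e <- spec@windEvents[i, ]
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    (rr - e$row)^2 + (cc - e$col)^2 <= e$radius^2
  })
  frames <- vector("list", n)
  transforms <- if (spec@jitterSigmaPx > 0 || spec@jitterSigmaDeg > 0)
    vector("list", n) else NULL
  for (t in seq_len(n)) {
    img <- background
    ie <- spec@illuminationEvents
    if (nrow(ie)) img <- img + sum(ie$offset[ie$frame <= t])
    for (i in seq_len(nrow(spec@windEvents))) {
      e <- spec@windEvents[i, ]
      ## fresh coherent zero-mean fluctuation each active frame
      fluct <- .smoothNoise(h, w, 2) * e$amplitude
      if (t >= e$startFrame && t <= e$endFrame)
        img[windMasks[[i]]] <- img[windMasks[[i]]] + fluct[windMasks[[i]]]
    }
    for (i in seq_len(nrow(spec@walkerEvents))) {
      e <- spec@walkerEvents[i, ]
      if (t < e$startFrame || t > e$endFrame) next
      frac <- if (e$endFrame > e$startFrame)
        (t - e$startFrame) / (e$endFrame - e$startFrame) else 0
      pos <- round(c(e$startRow + frac * (e$endRow - e$startRow),
                     e$startCol + frac * (e$endCol - e$startCol)))
      fp <- footprintCoords(pos[1L], pos[2L], e$size)
      ok <- fp[, 1L] >= 1 & fp[, 1L] <= h & fp[, 2L] >= 1 & fp[, 2L] <= w
      img[fp[ok, , drop = FALSE]] <- img[fp[ok, , drop = FALSE]] +
        sgn * e$contrast
    }
    for (i in seq_len(nrow(spec@sitterEvents))) {
      e <- spec@sitterEvents[i, ]
      jit <- round(stats::rnorm(2, 0, e$jitter))  # drawn every frame for determinism
      if (t < e$startFrame || t >= e$startFrame + e$dwell) next
      fp <- footprintCoords(e$row + jit[1L], e$col + jit[2L], e$size)
      ok <- fp[, 1L] >= 1 & fp[, 1L] <= h & fp[, 2L] >= 1 & fp[, 2L] <= w
      img[fp[ok, , drop = FALSE]] <- img[fp[ok, , drop = FALSE]] +
        sgn * e$contrast
    }
    for (i in seq_len(nrow(spec@dropEvents))) {
      e <- spec@dropEvents[i, ]
      if (t < e$frame) next
      contrast <- if (spec@channel == "LWIR")
        coolingCurve(e$contrast, e$tau, (t - e$frame) * dt) else e$contrast
      fp <- footprintCoords(e$row, e$col, e$size)
      img[fp] <- img[fp] + sgn * contrast
    }
    if (!is.null(transforms)) {
      tx <- stats::rnorm(1, 0, spec@jitterSigmaPx)
      ty <- stats::rnorm(1, 0, spec@jitterSigmaPx)
      th <- stats::rnorm(1, 0, spec@jitterSigmaDeg) * pi / 180
      cx <- (w + 1) / 2; cy <- (h + 1) / 2
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
      offs <- c(cx, cy) - rot %*% c(cx, cy) + c(tx, ty)
      A <- affineTransform(cbind(rot, offs))
      img <- warpImage(img, A, fill = "replicate")
      attr(img, "inside") <- NULL
      transforms[[t]] <- invertTransform(A)  # frame -> reference truth
    }
    if (spec@noiseSigma > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, spec@noiseSigma), h, w)
    img <- round(pmin(pmax(img, 0), 255))
    frames[[t]] <- Frame(img, timestamp = t * dt, channel = spec@channel,
                         frameId = t)
  }
  truth <- do.call(rbind, c(
    lapply(seq_len(nrow(spec@dropEvents)), function(i) {
      e <- spec@dropEvents[i, ]
      data.frame(type = "drop", frame = e$frame, time = e$frame * dt,
                 row = e$row, col = e$col, size = e$size)
    }),
    lapply(seq_len(nrow(spec@walkerEvents)), function(i) {
      e <- spec@walkerEvents[i, ]
      data.frame(type = "walker", frame = e$startFrame,
                 time = e$startFrame * dt, row = e$startRow,
                 col = e$startCol, size = e$size)
    }),
    lapply(seq_len(nrow(spec@sitterEvents)), function(i) {
      e <- spec@sitterEvents[i, ]
      data.frame(type = "sitter", frame = e$startFrame,
                 time = e$startFrame * dt, row = e$row, col = e$col,
                 size = e$size)
    }),
    lapply(seq_len(nrow(spec@windEvents)), function(i) {
      e <- spec@windEvents[i, ]
      data.frame(type = "wind", frame = e$startFrame,
                 time = e$startFrame * dt, row = e$row, col = e$col,
                 size = NA_real_)
    }),
    lapply(seq_len(nrow(spec@illuminationEvents)), function(i) {
      e <- spec@illuminationEvents[i, ]
      data.frame(type = "illumination", frame = e$frame, time = e$frame * dt,
                 row = NA_real_, col = NA_real_, size = NA_real_)
    })
  ))
  if (is.null(truth))
    truth <- data.frame(type = character(0), frame = numeric(0),
                        time = numeric(0), row = numeric(0),
                        col = numeric(0), size = numeric(0))
  list(frames = frames, truth = truth, transforms = transforms)
}
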