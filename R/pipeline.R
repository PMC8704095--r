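## pipeline: orchestration of the stage order over a frame sequence.
##
## register -> brightness normalization -> pixel score -> adaptive
## threshold -> region generation -> preselection -> structural decision,
## evaluated once per new frame on the rolling stack.

#' Build a detector configuration with channel-resolved defaults
#'
#' LWIR defaults: no brightness normalization (the thermal camera's gain
#' control is in-camera), no morphological opening (a fatality can be a
#' single pixel at the thermal ground resolution), threshold offset 3.
#' VIS defaults: median brightness normalization, opening radius 1,
#' threshold offset 5.
#'
#' @param channel camera channel
#' @param halfSize,excludeMiddle,frameInterval stack parameters
#' @param register align every frame to the sequence reference; disable
#'   for input known to be pixel-aligned
#' @param minKeypoints,searchRadius,patchRadius registration parameters
#' @param normalizeBrightness override the channel default
#' @param scoring a \linkS4class{ScoringConfig}
#' @param blockSize,thresholdOffset adaptive-threshold parameters
#' @param openingRadius,dilateIters,gapIters region-generation morphology
#' @param preselection a \linkS4class{PreselectionThresholds}
#' @param structural a \linkS4class{StructuralThresholds}
#' @param maxMaskedFraction discard regions more masked than this
#' @param dedupWindow suppress repeat detections of the same object within
#'   this many stack positions (default: halfSize)
#' @param seed integer seed for the stochastic registration fit
#' @return a \linkS4class{DetectorConfig}
#' @export
detectorConfig <- function(channel = c("LWIR", "VIS"), halfSize = 5L,
                           excludeMiddle = FALSE, frameInterval = 10,
                           register = TRUE, minKeypoints = 8L,
                           searchRadius = 14L, patchRadius = 5L,
                           normalizeBrightness = NULL,
                           scoring = NULL, blockSize = 31L,
                           thresholdOffset = NULL, openingRadius = NULL,
                           dilateIters = 3L, gapIters = 1L,
                           preselection = NULL, structural = NULL,
                           maxMaskedFraction = 0.2, dedupWindow = NULL,
                           seed = 1L) {
  channel <- match.arg(channel)
  if (is.null(normalizeBrightness)) normalizeBrightness <- channel == "VIS"
  if (is.null(scoring)) scoring <- scoringConfig(channel)
  if (is.null(thresholdOffset))
    thresholdOffset <- if (channel == "LWIR") 3 else 5
  if (is.null(openingRadius))
    openingRadius <- if (channel == "LWIR") 0L else 1L
  if (is.null(preselection)) preselection <- preselectionThresholds(channel)
  if (is.null(structural)) structural <- structuralThresholds()
  if (is.null(dedupWindow)) dedupWindow <- halfSize
  new("DetectorConfig", channel = channel, halfSize = as.integer(halfSize),
      excludeMiddle = excludeMiddle, frameInterval = as.numeric(frameInterval),
      register = register, minKeypoints = as.integer(minKeypoints),
      searchRadius = as.integer(searchRadius),
      patchRadius = as.integer(patchRadius),
      normalizeBrightness = normalizeBrightness, scoring = scoring,
      blockSize = as.integer(blockSize),
      thresholdOffset = as.numeric(thresholdOffset),
      openingRadius = as.integer(openingRadius),
      dilateIters = as.integer(dilateIters), gapIters = as.integer(gapIters),
      preselection = preselection, structural = structural,
      maxMaskedFraction = as.numeric(maxMaskedFraction),
      dedupWindow = as.integer(dedupWindow), seed = as.integer(seed))
}

#' Run the detection pipeline over a frame sequence
#'
#' Frames are registered to the sequence reference (the first frame),
#' pushed onto the rolling stack and, at every full stack position,
#' normalized, scored, thresholded, segmented into candidate regions and
#' judged by the preselection and structural criteria. A frame whose
#' registration fails is skipped with a warning rather than crashing the
#' run. Accepted candidates whose centroid falls within twice the region
#' diagonal of an event raised in the previous \code{dedupWindow} stack
#' positions are merged into that event (a dropped object stays visible
#' in many consecutive stacks).
#'
#' @param frames list of \linkS4class{Frame}s (>= 2 * halfSize), uniform
#'   shape and channel
#' @param config a \linkS4class{DetectorConfig}
#' @param verbose log per-stage information to stderr
#' @return list of \linkS4class{DetectionEvent}
#' @export
processSequence <- function(frames, config = detectorConfig(), verbose = FALSE) {
  if (length(frames) < 2L * config@halfSize)
    stop("need at least 2 * halfSize frames")
  stack <- ImageStack(config@halfSize, config@excludeMiddle,
                      config@frameInterval)
  events <- list()
  recent <- list()   # accepted candidates (incl. duplicates): pos, centroid, diag
  ref <- NULL
  pos <- 0L
  for (f in frames) {
    if (config@register) {
      if (is.null(ref)) {
        ref <- f
        wf <- f
      } else {
        tr <- tryCatch(
          estimateAlignment(f, ref, minKeypoints = config@minKeypoints,
                            searchRadius = config@searchRadius,
                            patchRadius = config@patchRadius,
                            seed = config@seed + f@frameId),
          error = function(e) e)
        if (inherits(tr, "error")) {
          warning(sprintf("frame %d: registration failed (%s); frame skipped",
                          f@frameId, conditionMessage(tr)))
          next
        }
        if (verbose)
          message(sprintf("frame %d: %d inliers, residual %.2f px",
                          f@frameId, tr@nInliers, tr@residual))
        wf <- warpToReference(f, tr)
      }
    } else {
      wf <- f
    }
    stack <- pushFrame(stack, wf)
    if (!isFull(stack)) next
    pos <- pos + 1L
    t0 <- proc.time()[[3L]]
    work <- if (config@normalizeBrightness)
      normalizeStack(stack, force = TRUE) else stack
    sm <- scoreStack(work, config@scoring)
    bin <- adaptiveThreshold(sm, config@blockSize, config@thresholdOffset)
    if (any(bin)) {
      rs <- generateRegions(bin, config@openingRadius, config@dilateIters,
                            config@gapIters)
      for (region in rs@regions) {
        ev <- evaluateCandidate(region, work, sm, config@preselection,
                                config@structural, config@maxMaskedFraction)
        if (ev@verdict != "detected") next
        diag <- sqrt((region$bbox[2L] - region$bbox[1L] + 1)^2 +
                       (region$bbox[4L] - region$bbox[3L] + 1)^2)
        dup <- FALSE
        for (rc in recent) {
          if (pos - rc$pos > config@dedupWindow) next
          d <- sqrt(sum((rc$centroid - region$centroid)^2))
          if (d <= 2 * max(diag, rc$diag)) { dup <- TRUE; break }
        }
        recent <- c(recent, list(list(pos = pos, centroid = region$centroid,
                                      diag = diag)))
        if (dup) next
        tFrame <- stack@frames[[config@halfSize + 1L]]
        events <- c(events, new("DetectionEvent",
          timestamp = tFrame@timestamp, centroid = region$centroid,
          area = as.integer(region$area), channel = channel(stack),
          frameIds = vapply(stack@frames, function(x) x@frameId, integer(1)),
          criteria = list(values = ev@criterionValues,
                          preselection = config@preselection,
                          structural = config@structural),
          sdiffs = ev@sdiffSeries))
      }
    }
    if (verbose)
      message(sprintf("stack position %d evaluated in %.3f s", pos,
                      proc.time()[[3L]] - t0))
  }
  events
}

#' Detection events as a data frame
#'
#' @param events list of \linkS4class{DetectionEvent}
#' @return data.frame with one row per event (timestamp, row, col, area,
#'   channel and the main criterion values)
#' @export
eventsToDataFrame <- function(events) {
  if (length(events) == 0L)
    return(data.frame(timestamp = numeric(0), row = numeric(0),
                      col = numeric(0), area = integer(0),
                      channel = character(0), middleSdiff = numeric(0),
                      maxSideSdiff = numeric(0)))
  do.call(rbind, lapply(events, function(e) {
    v <- e@criteria$values
    data.frame(timestamp = e@timestamp, row = e@centroid[1L],
               col = e@centroid[2L], area = e@area, channel = e@channel,
               middleSdiff = if (is.null(v$middleSdiff)) NA_real_ else v$middleSdiff,
               maxSideSdiff = if (is.null(v$maxSideSdiff)) NA_real_ else v$maxSideSdiff)
  }))
}

#' Write detection events as JSON Lines
#'
#' One JSON object per event with the full criteria record and the
#' thresholds in force.
#'
#' @param events list of \linkS4class{DetectionEvent}
#' @param path output file
#' @export
writeEventsJsonl <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in events) {
    pre <- e@criteria$preselection
    st <- e@criteria$structural
    rec <- list(
      timestamp = e@timestamp, row = e@centroid[1L], col = e@centroid[2L],
      area = e@area, channel = e@channel, frame_ids = e@frameIds,
      verdict = "detected", criteria = e@criteria$values,
      sdiff_series = e@sdiffs,
      thresholds = list(
        area_min = pre@areaMin, area_max = pre@areaMax,
        temporal_min = pre@temporalMin, spatial_min = pre@spatialMin,
        surround_max = pre@surroundMax,
        middle_sdiff_min = st@middleSdiffMin,
        side_sdiff_max = st@sideSdiffMax,
        sdiff_quotient_min = st@sdiffQuotientMin))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
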