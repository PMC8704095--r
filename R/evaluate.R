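## evaluate: detections vs. ground truth, and the arithmetic of the
## headline measures (sensitivity, false positives per hour).

#' Match detection events to ground-truth drop events
#'
#' Greedy nearest matching: event/truth pairs within \code{radiusPx} and
#' \code{timeWindow} are matched closest-first; each truth event is
#' matched at most once. Unmatched truth events are false negatives,
#' unmatched detections false positives.
#'
#' @param events list of \linkS4class{DetectionEvent} (or a data.frame
#'   from \code{\link{eventsToDataFrame}})
#' @param truth ground-truth data.frame with columns \code{type},
#'   \code{time}, \code{row}, \code{col}; only \code{type == "drop"} rows
#'   are expected detections
#' @param radiusPx spatial match radius in pixels
#' @param timeWindow temporal match window in seconds
#' @return list with counts \code{tp}, \code{fn}, \code{fp} and a
#'   \code{matches} data.frame of matched pairs with spatial and temporal
#'   residuals
#' @export
matchDetections <- function(events, truth, radiusPx = 5, timeWindow = 100) {
  stopifnot(radiusPx > 0, timeWindow > 0)
  ev <- if (is.data.frame(events)) events else eventsToDataFrame(events)
  drops <- truth[truth$type == "drop", , drop = FALSE]
  nE <- nrow(ev); nT <- nrow(drops)
  matches <- data.frame(event = integer(0), truth = integer(0),
                        dist = numeric(0), dt = numeric(0))
  if (nE && nT) {
    cand <- expand.grid(event = seq_len(nE), truth = seq_len(nT))
    cand$dist <- sqrt((ev$row[cand$event] - drops$row[cand$truth])^2 +
                        (ev$col[cand$event] - drops$col[cand$truth])^2)
    cand$dt <- abs(ev$timestamp[cand$event] - drops$time[cand$truth])
    cand <- cand[cand$dist <= radiusPx & cand$dt <= timeWindow, , drop = FALSE]
    cand <- cand[order(cand$dist, cand$dt), , drop = FALSE]
    usedE <- logical(nE); usedT <- logical(nT)
    for (i in seq_len(nrow(cand))) {
      e <- cand$event[i]; t <- cand$truth[i]
      if (usedE[e] || usedT[t]) next
      usedE[e] <- TRUE; usedT[t] <- TRUE
      matches <- rbind(matches, cand[i, ])
    }
  }
  list(tp = nrow(matches), fn = nT - nrow(matches),
       fp = nE - nrow(matches), matches = matches)
}

#' Detection sensitivity in percent
#'
#' \code{100 * tp / (tp + fn)}, reported half-up to one decimal, the
#' printed precision of field drop-test tables.
#'
#' @param tp,fn true-positive and false-negative counts
#' @return percentage, one decimal
#' @export
sensitivity <- function(tp, fn) {
  if (tp + fn <= 0) stop("sensitivity undefined: tp + fn must be > 0")
  roundHalfUp(100 * tp / (tp + fn), 1L)
}

#' False positives per monitored hour
#'
#' @param fp false-positive count
#' @param duration monitored duration in hours (> 0)
#' @return rate per hour, two decimals (half-up)
#' @export
fpRate <- function(fp, duration) {
  if (duration <= 0) stop("duration must be positive")
  roundHalfUp(fp / duration, 2L)
}

#' Build a per-stratum evaluation report
#'
#' One row per stratum (e.g., drop position or surface type) with its
#' counts and sensitivity, plus a totals row; the false-positive rate is
#' computed over the summed duration. Free-text annotations (e.g., the
#' suspected cause of each false positive) are passed through.
#'
#' @param results list of strata; each a list with \code{label},
#'   \code{match} (from \code{\link{matchDetections}} or a list with tp,
#'   fn, fp), \code{duration} (hours) and optional \code{notes}
#' @return data.frame with columns label, duration, tp, fn, fp,
#'   sensitivity, fpRate, notes
#' @export
buildReport <- function(results) {
  stopifnot(length(results) > 0L)
  rows <- lapply(results, function(s) {
    m <- s$match
    data.frame(label = s$label,
               duration = if (is.null(s$duration)) NA_real_ else s$duration,
               tp = m$tp, fn = m$fn, fp = m$fp,
               sensitivity = if (m$tp + m$fn > 0)
                 sensitivity(m$tp, m$fn) else NA_real_,
               fpRate = if (!is.null(s$duration) && !is.na(s$duration))
                 fpRate(m$fp, s$duration) else NA_real_,
               notes = if (is.null(s$notes)) "" else s$notes)
  })
  rep <- do.call(rbind, rows)
  totTp <- sum(rep$tp); totFn <- sum(rep$fn); totFp <- sum(rep$fp)
  totDur <- sum(rep$duration, na.rm = TRUE)
  total <- data.frame(
    label = "all", duration = totDur, tp = totTp, fn = totFn, fp = totFp,
    sensitivity = if (totTp + totFn > 0) sensitivity(totTp, totFn)
      else NA_real_,
    fpRate = if (totDur > 0) fpRate(totFp, totDur) else NA_real_,
    notes = "")
  out <- rbind(rep, total)
  rownames(out) <- NULL
  out
}
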