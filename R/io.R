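## io: reading and writing image sequences and ground truth.

#' Read a grayscale frame sequence from a directory
#'
#' PNG or TIFF files, sorted by name. Timestamps are parsed from
#' ISO-8601-style filenames (\code{YYYYMMDDTHHMMSS.*}) or taken from a
#' sidecar CSV with columns \code{filename} and \code{unix_timestamp}.
#'
#' @param dir directory of image files
#' @param channel channel tag for the frames
#' @param timestamps optional path to the sidecar CSV
#' @return list of \linkS4class{Frame}
#' @export
readFrameSequence <- function(dir, channel = c("VIS", "LWIR"),
                              timestamps = NULL) {
  channel <- match.arg(channel)
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no PNG/TIFF files in ", dir)
  if (!is.null(timestamps)) {
    tsv <- utils::read.csv(timestamps, stringsAsFactors = FALSE)
    ts <- tsv$unix_timestamp[match(files, tsv$filename)]
    if (anyNA(ts)) stop("timestamp CSV is missing entries for some files")
  } else {
    stamps <- regmatches(files, regexpr("\\d{8}T\\d{6}", files))
    if (length(stamps) != length(files))
      stop("filenames do not carry YYYYMMDDTHHMMSS timestamps; ",
           "provide a sidecar CSV")
    ts <- as.numeric(as.POSIXct(stamps, format = "%Y%m%dT%H%M%S", tz = "UTC"))
  }
  ord <- order(ts)
  mapply(function(fn, t, id) {
    img <- EBImage::readImage(file.path(dir, fn))
    px <- EBImage::imageData(img)
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    ## EBImage stores (x, y); transpose to (row, col)
    Frame(t(px) * 255, timestamp = t, channel = channel, frameId = id)
  }, files[ord], ts[ord], seq_along(files), SIMPLIFY = FALSE)
}

#' Write a frame sequence as PNG files plus CSV sidecars
#'
#' @param frames list of \linkS4class{Frame}
#' @param dir output directory (created if absent)
#' @param truth optional ground-truth data.frame to write as
#'   \code{truth.csv}
#' @return \code{dir}, invisibly
#' @export
writeFrameSequence <- function(frames, dir, truth = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fns <- sprintf("frame_%04d.png", seq_along(frames))
  for (i in seq_along(frames)) {
    px <- t(frames[[i]]@pixels) / 255
    EBImage::writeImage(px, file.path(dir, fns[i]))
  }
  utils::write.csv(
    data.frame(filename = fns,
               unix_timestamp = vapply(frames, function(f) f@timestamp,
                                       numeric(1))),
    file.path(dir, "timestamps.csv"), row.names = FALSE)
  if (!is.null(truth))
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write detection events as CSV
#'
#' @param events list of \linkS4class{DetectionEvent}
#' @param path output file
#' @export
writeEventsCsv <- function(events, path) {
  utils::write.csv(eventsToDataFrame(events), path, row.names = FALSE)
  invisible(path)
}
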