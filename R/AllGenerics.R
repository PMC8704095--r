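#' Push a frame onto an image stack
#'
#' Appends \code{frame} to the FIFO window, evicting the oldest frame once
#' the stack already holds \code{2 * halfSize(stack)} frames. The frame
#' must match the stack's shape and channel and carry a timestamp strictly
#' greater than the newest held frame.
#'
#' @param stack an \linkS4class{ImageStack}
#' @param frame a \linkS4class{Frame}
#' @return the updated \linkS4class{ImageStack}
#' @export
setGeneric("pushFrame", function(stack, frame) standardGeneric("pushFrame"))

#' Split a full stack into its old and new halves
#'
#' The older N frames are the \emph{old} half, the newer N the \emph{new}
#' half. With \code{excludeMiddle} the innermost frame of each half (the
#' pair straddling the assumed strike) is omitted, so each returned half
#' has N - 1 frames.
#'
#' @param stack a full \linkS4class{ImageStack}
#' @return list with elements \code{old} and \code{new}, each a list of
#'   \linkS4class{Frame}
#' @export
setGeneric("splitHalves", function(stack) standardGeneric("splitHalves"))

#' Is the stack holding its full complement of frames?
#' @param stack an \linkS4class{ImageStack}
#' @return logical
#' @export
setGeneric("isFull", function(stack) standardGeneric("isFull"))

#' Median brightness normalization of a full stack
#'
#' @param stack a full, registered \linkS4class{ImageStack}
#' @param ... passed to methods; see \code{\link{adjustMedian}}
#' @return the normalized \linkS4class{ImageStack}
#' @export
setGeneric("normalizeStack",
           function(stack, ...) standardGeneric("normalizeStack"))

#' Frames held by a stack
#' @param x an \linkS4class{ImageStack}
#' @return list of \linkS4class{Frame}
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' Stack half size N
#' @param x an \linkS4class{ImageStack}
#' @return integer
#' @export
setGeneric("halfSize", function(x) standardGeneric("halfSize"))

#' Channel tag of an object
#' @param x a \linkS4class{Frame}, \linkS4class{ImageStack} or
#'   \linkS4class{ScoreMap}
#' @return \code{"VIS"} or \code{"LWIR"} (NA for an empty stack)
#' @export
setGeneric("channel", function(x) standardGeneric("channel"))

#' Pixel matrix of a Frame
#' @param x a \linkS4class{Frame}
#' @return numeric matrix
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Score matrix of a ScoreMap
#' @param x a \linkS4class{ScoreMap}
#' @return numeric matrix with \code{NA} at masked pixels
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Candidate regions of a RegionSet
#' @param x a \linkS4class{RegionSet}
#' @return list of region records
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
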