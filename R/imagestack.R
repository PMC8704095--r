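## imagestack: the FIFO temporal window and its halves.

#' @rdname pushFrame
setMethod("pushFrame", signature("ImageStack", "Frame"),
  function(stack, frame) {
    n <- length(stack@frames)
    if (n > 0L) {
      last <- stack@frames[[n]]
      if (!identical(dim(last@pixels), dim(frame@pixels)))
        stop("frame shape does not match the stack")
      if (!identical(last@channel, frame@channel))
        stop("frame channel does not match the stack")
      if (frame@timestamp <= last@timestamp)
        stop("frame timestamp must exceed the newest timestamp in the stack")
      dt <- frame@timestamp - last@timestamp
      if (abs(dt - stack@frameInterval) > 0.1 * stack@frameInterval)
        warning(sprintf(
          "irregular frame interval: %.2fs (nominal %.2fs); scoring is index-based",
          dt, stack@frameInterval))
    }
    stack@frames <- c(stack@frames, frame)
    if (length(stack@frames) > 2L * stack@halfSize)
      stack@frames <- stack@frames[-1L]
    validObject(stack)
    stack
  })

#' @rdname isFull
setMethod("isFull", "ImageStack", function(stack) {
  length(stack@frames) == 2L * stack@halfSize
})

#' @rdname splitHalves
setMethod("splitHalves", "ImageStack", function(stack) {
  N <- stack@halfSize
  if (!isFull(stack))
    stop(sprintf("insufficient history: stack holds %d of %d frames",
                 length(stack@frames), 2L * N))
  old <- stack@frames[seq_len(N)]
  new <- stack@frames[N + seq_len(N)]
  if (stack@excludeMiddle) {
    old <- old[-N]      # drop I_{T-1}
    new <- new[-1L]     # drop I_T
  }
  list(old = old, new = new)
})

#' @rdname frames
setMethod("frames", "ImageStack", function(x) x@frames)

#' @rdname halfSize
setMethod("halfSize", "ImageStack", function(x) x@halfSize)

#' @rdname channel
setMethod("channel", "ImageStack", function(x) {
  if (length(x@frames) == 0L) NA_character_ else x@frames[[1L]]@channel
})

#' @rdname channel
setMethod("channel", "Frame", function(x) x@channel)

#' @rdname pixels
setMethod("pixels", "Frame", function(x) x@pixels)

#' @rdname channel
setMethod("channel", "ScoreMap", function(x) x@channel)

#' @rdname scores
setMethod("scores", "ScoreMap", function(x) x@scores)

#' @rdname regions
setMethod("regions", "RegionSet", function(x) x@regions)

#' Stack pixel data as a 3-D array
#'
#' @param stack a full \linkS4class{ImageStack}
#' @return numeric array rows x cols x frames (oldest first)
#' @export
stackArray <- function(stack) {
  fs <- stack@frames
  d <- dim(fs[[1L]]@pixels)
  array(unlist(lapply(fs, function(f) f@pixels)),
        dim = c(d, length(fs)))
}

#' Joint validity mask of a stack (valid in every frame)
#'
#' @param stack an \linkS4class{ImageStack}
#' @return logical matrix
#' @export
stackMask <- function(stack) {
  m <- stack@frames[[1L]]@mask
  for (f in stack@frames[-1L]) m <- m & f@mask
  m
}
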