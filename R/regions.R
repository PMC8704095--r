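## regions: from a score map to labeled candidate regions.
##
## Adaptive (local-mean) thresholding finds local maxima regardless of
## absolute level, so shadowed and sunlit parts of the scene are treated
## alike. Morphological opening (VIS only by default) removes speckle,
## dilation merges near pixels and adds the surround, and 8-connected
## labeling on the dilated map defines the full regions. Doing the
## labeling once, after all morphology, guarantees equal numbers of inner,
## outer and full sets.

#' Adaptive local-mean thresholding of a score map
#'
#' A pixel is set iff its score exceeds the mean score of its
#' \code{blockSize x blockSize} neighborhood (clipped at the border,
#' masked pixels excluded from the mean) by more than \code{offset}.
#' Masked pixels are never set.
#'
#' @param score a \linkS4class{ScoreMap}
#' @param blockSize odd neighborhood side length, >= 3 and smaller than
#'   the image
#' @param offset additive margin above the local mean, in score units
#' @return logical matrix (the binary candidate map)
#' @export
adaptiveThreshold <- function(score, blockSize = 31L, offset = 5) {
  s <- score@scores
  blockSize <- as.integer(blockSize)
  if (blockSize < 3L || blockSize %% 2L == 0L)
    stop("blockSize must be an odd integer >= 3")
  if (blockSize >= min(dim(s)))
    stop("blockSize must be smaller than the image")
  r <- (blockSize - 1L) %/% 2L
  valid <- score@mask
  sv <- s
  sv[!valid] <- 0
  localSum <- boxSum(sv, r)
  localN <- boxSum(matrix(as.numeric(valid), nrow(s)), r)
  localMean <- localSum / pmax(localN, 1)
  out <- valid & !is.na(s) & (s > localMean + offset)
  out[is.na(out)] <- FALSE
  out
}

## 8-connected component labeling via union-find (EBImage's labeling is
## 4-connected, which would split diagonal pixel pairs the detector must
## treat as one object).
labelComponents8 <- function(binary) {
  h <- nrow(binary); w <- ncol(binary)
  lin <- which(binary)
  lab <- matrix(0L, h, w)
  if (length(lin) == 0L) return(lab)
  id <- integer(h * w)
  id[lin] <- seq_along(lin)
  parent <- seq_along(lin)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  rows <- ((lin - 1L) %% h) + 1L
  cols <- ((lin - 1L) %/% h) + 1L
  for (off in list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L))) {
    ok <- rows + off[1L] >= 1L & rows + off[1L] <= h &
      cols + off[2L] >= 1L & cols + off[2L] <= w
    nlin <- lin[ok] + off[1L] + off[2L] * h
    sel <- which(ok)[id[nlin] > 0L]
    if (!length(sel)) next
    a <- id[lin[sel]]
    b <- id[lin[sel] + off[1L] + off[2L] * h]
    for (k in seq_along(a)) {
      ra <- findRoot(a[k]); rb <- findRoot(b[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(lin), findRoot, integer(1))
  lab[lin] <- match(roots, unique(roots))
  lab
}

#' Generate candidate regions from a binary map
#'
#' Pipeline: optional morphological opening (removes clusters smaller
#' than the structuring element; skipped by default on LWIR where a
#' fatality can be a single pixel), dilation (merges near pixels and adds
#' the surround), 8-connected labeling of the dilated map into full
#' regions, and per label: \code{inner} = the pre-dilation thresholded
#' pixels of the region, \code{outer} = full minus the \code{gapIters}
#' dilation of inner, leaving a separating gap.
#'
#' @param binary logical candidate map (from
#'   \code{\link{adaptiveThreshold}})
#' @param openingRadius box radius of the opening structuring element;
#'   0 skips opening
#' @param dilateIters Chebyshev radius of the dilation
#' @param gapIters Chebyshev width of the inner/outer separating gap
#' @return a \linkS4class{RegionSet} (empty for an empty map)
#' @export
generateRegions <- function(binary, openingRadius = 1L, dilateIters = 3L,
                            gapIters = 1L) {
  stopifnot(openingRadius >= 0L, dilateIters >= 0L, gapIters >= 0L)
  dm <- dim(binary)
  opened <- binary
  if (openingRadius > 0L && any(binary)) {
    opened <- EBImage::opening(
      matrix(as.numeric(binary), dm[1L]),
      EBImage::makeBrush(2L * as.integer(openingRadius) + 1L, "box")) > 0.5
  }
  if (!any(opened))
    return(new("RegionSet", regions = list(), dim = as.integer(dm)))
  dilated <- dilateMask(opened, dilateIters)
  lab <- labelComponents8(dilated)
  regs <- vector("list", max(lab))
  for (k in seq_len(max(lab))) {
    fullMask <- lab == k
    innerMask <- fullMask & opened
    if (!any(innerMask)) {
      ## single-pixel fallback: seed from the region's first pixel
      innerMask[which(fullMask)[1L]] <- TRUE
    }
    outerMask <- fullMask & !dilateMask(innerMask, gapIters)
    inner <- maskToCoords(innerMask)
    full <- maskToCoords(fullMask)
    regs[[k]] <- list(
      label = k,
      inner = inner,
      outer = maskToCoords(outerMask),
      full = full,
      centroid = colMeans(inner),
      area = nrow(inner),
      bbox = c(range(full[, 1L]), range(full[, 2L]))
    )
  }
  new("RegionSet", regions = regs, dim = as.integer(dm))
}
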