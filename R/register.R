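## register: align frames to a reference despite nacelle motion.
##
## Keypoints are Harris corners; correspondence comes from normalized
## cross-correlation of gray patches in a local search window with subpixel
## peak refinement; the affine fit is a random-sample consensus over the
## matches. The contract is pixel-precision alignment (<= 1 px median
## residual on inliers).

#' Construct an AffineTransform from its 2x3 coefficient matrix
#'
#' Coordinates are (x = column, y = row): the transform maps
#' \code{(x', y')^T = A \%*\% c(x, y, 1)} from moving-frame into
#' reference-frame pixel coordinates.
#'
#' @param coefficients 2x3 numeric matrix with non-singular linear part
#' @param nInliers,residual optional provenance of an estimated transform
#' @return an \linkS4class{AffineTransform}
#' @export
affineTransform <- function(coefficients, nInliers = 0L, residual = 0) {
  new("AffineTransform", coefficients = coefficients,
      nInliers = as.integer(nInliers), residual = as.numeric(residual))
}

#' The identity transform
#' @return an \linkS4class{AffineTransform}
#' @export
identityTransform <- function() {
  affineTransform(cbind(diag(2), c(0, 0)))
}

#' Invert an affine transform
#' @param transform an \linkS4class{AffineTransform}
#' @return the inverse \linkS4class{AffineTransform}
#' @export
invertTransform <- function(transform) {
  a <- transform@coefficients
  li <- solve(a[, 1:2])
  affineTransform(cbind(li, -li %*% a[, 3L]),
                  transform@nInliers, transform@residual)
}

#' Compose two affine transforms (apply \code{inner} first)
#' @param outer,inner \linkS4class{AffineTransform}s
#' @return their composition as an \linkS4class{AffineTransform}
#' @export
composeTransforms <- function(outer, inner) {
  ao <- outer@coefficients; ai <- inner@coefficients
  lin <- ao[, 1:2] %*% ai[, 1:2]
  off <- ao[, 1:2] %*% ai[, 3L] + ao[, 3L]
  affineTransform(cbind(lin, off))
}

#' Apply a transform to (row, col) points
#'
#' @param transform an \linkS4class{AffineTransform}
#' @param points n x 2 matrix of (row, col) coordinates
#' @return n x 2 matrix of transformed (row, col) coordinates
#' @export
transformPoints <- function(transform, points) {
  points <- rbind(points)
  a <- transform@coefficients
  xy <- cbind(points[, 2L], points[, 1L], 1)  # to (x, y, 1)
  out <- xy %*% t(a)
  cbind(out[, 2L], out[, 1L])
}

## Harris corner detection. Returns (row, col) matrix ordered by corner
## strength, thinned to a minimum mutual distance, away from the border.
detectCorners <- function(px, maxCorners = 40L, minDistance = 8L,
                          qualityLevel = 0.01, margin = 4L, k = 0.04) {
  h <- nrow(px); w <- ncol(px)
  g <- px / 255
  ix <- matrix(0, h, w); iy <- matrix(0, h, w)
  ix[, 2:(w - 1)] <- (g[, 3:w] - g[, 1:(w - 2)]) / 2
  iy[2:(h - 1), ] <- (g[3:h, ] - g[1:(h - 2), ]) / 2
  sxx <- EBImage::gblur(ix * ix, sigma = 1.5)
  syy <- EBImage::gblur(iy * iy, sigma = 1.5)
  sxy <- EBImage::gblur(ix * iy, sigma = 1.5)
  resp <- (sxx * syy - sxy * sxy) - k * (sxx + syy)^2
  top <- max(resp)
  if (!is.finite(top) || top <= 0) return(matrix(integer(0), 0L, 2L))
  ## 3x3 non-maximum suppression
  mx <- matrix(-Inf, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    rs <- pmin(pmax(seq_len(h) + dr, 1L), h)
    cs <- pmin(pmax(seq_len(w) + dc, 1L), w)
    mx <- pmax(mx, resp[rs, cs])
  }
  cand <- which(resp >= mx & resp > qualityLevel * top, arr.ind = TRUE)
  keep <- cand[, 1L] > margin & cand[, 1L] <= h - margin &
    cand[, 2L] > margin & cand[, 2L] <= w - margin
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(matrix(integer(0), 0L, 2L))
  ord <- order(resp[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  sel <- matrix(integer(0), 0L, 2L)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(sel) == 0L ||
        min(pmax(abs(sel[, 1L] - p[1L]), abs(sel[, 2L] - p[2L]))) >= minDistance)
      sel <- rbind(sel, p)
    if (nrow(sel) >= maxCorners) break
  }
  dimnames(sel) <- NULL
  sel
}

## Normalized cross-correlation of a reference patch inside a moving-frame
## search window; returns the subpixel (row, col) of the best match in
## moving coordinates plus the correlation peak, or NULL when out of view.
nccMatch <- function(moving, refPx, pt, patchRadius, searchRadius) {
  h <- nrow(moving); w <- ncol(moving)
  pr <- patchRadius; sr <- searchRadius
  r <- pt[1L]; c <- pt[2L]
  if (r - pr < 1L || r + pr > h || c - pr < 1L || c + pr > w) return(NULL)
  patch <- refPx[(r - pr):(r + pr), (c - pr):(c + pr)]
  p0 <- patch - mean(patch)
  sdp <- sqrt(mean(p0 * p0))
  if (sdp < 1e-9) return(NULL)
  r1 <- r - sr - pr; r2 <- r + sr + pr
  c1 <- c - sr - pr; c2 <- c + sr + pr
  if (r1 < 1L || r2 > h || c1 < 1L || c2 > w) {
    sr <- min(sr, r - pr - 1L, h - r - pr, c - pr - 1L, w - c - pr)
    if (sr < 2L) return(NULL)
    r1 <- r - sr - pr; r2 <- r + sr + pr
    c1 <- c - sr - pr; c2 <- c + sr + pr
  }
  S <- moving[r1:r2, c1:c2]
  n <- (2 * pr + 1)^2
  ## filter2 convolves (flips the kernel); flip the patch to correlate
  p0r <- p0[rev(seq_len(nrow(p0))), rev(seq_len(ncol(p0)))]
  num <- EBImage::filter2(S, p0r / n)       # mean of S * p0 per window
  sumS <- boxSum(S, pr)
  sumS2 <- boxSum(S * S, pr)
  varS <- pmax(sumS2 / n - (sumS / n)^2, 0)
  ncc <- num / (sqrt(varS) * sdp + 1e-12)
  side <- 2L * (sr + pr) + 1L
  valid <- matrix(FALSE, side, side)
  valid[(pr + 1L):(side - pr), (pr + 1L):(side - pr)] <- TRUE
  ncc[!valid] <- -Inf
  peak <- which.max(ncc)
  pi <- arrayInd(peak, dim(ncc))
  best <- ncc[peak]
  ## subpixel refinement: separable parabola through the 3-point neighborhood
  dr <- dc <- 0
  if (pi[1L] > 1L && pi[1L] < side && pi[2L] > 1L && pi[2L] < side) {
    a <- ncc[pi[1L] - 1L, pi[2L]]; b <- ncc[pi[1L] + 1L, pi[2L]]
    den <- a + b - 2 * best
    if (is.finite(a) && is.finite(b) && den < -1e-12)
      dr <- 0.5 * (a - b) / den
    a <- ncc[pi[1L], pi[2L] - 1L]; b <- ncc[pi[1L], pi[2L] + 1L]
    den <- a + b - 2 * best
    if (is.finite(a) && is.finite(b) && den < -1e-12)
      dc <- 0.5 * (a - b) / den
  }
  list(pos = c(r1 + pi[1L] - 1 + dr, c1 + pi[2L] - 1 + dc), score = best)
}

## Least-squares affine fit mapping mov (x, y) onto ref (x, y).
fitAffine <- function(mov, ref) {
  X <- cbind(mov, 1)
  a <- tryCatch(solve(crossprod(X), crossprod(X, ref)),
                error = function(e) NULL)
  if (is.null(a)) return(NULL)
  t(a)  # 2x3
}

#' Estimate the affine alignment of a moving frame onto a reference
#'
#' Harris corners detected in the reference are located in the moving
#' frame by normalized cross-correlation within a local search window
#' (with subpixel peak refinement); a seedable random-sample consensus
#' then fits the full affine transform over the matches.
#'
#' @param moving,reference \linkS4class{Frame}s or numeric matrices of the
#'   same shape; the reference needs detectable texture
#' @param minKeypoints minimum number of matched keypoints (and consensus
#'   inliers) required; fewer raises an untextured-scene error
#' @param maxCorners keypoint budget
#' @param searchRadius half-size of the correlation search window in px
#' @param patchRadius half-size of the descriptor patch in px
#' @param ransacIter consensus sampling iterations
#' @param inlierTol inlier residual tolerance in px
#' @param nccMin discard matches with a correlation peak below this
#' @param seed optional integer seed for the consensus sampling
#' @return an \linkS4class{AffineTransform} mapping moving onto reference,
#'   with inlier count and median residual recorded
#' @export
estimateAlignment <- function(moving, reference, minKeypoints = 8L,
                              maxCorners = 40L, searchRadius = 14L,
                              patchRadius = 5L, ransacIter = 300L,
                              inlierTol = 1.0, nccMin = 0.5, seed = NULL) {
  movPx <- if (is(moving, "Frame")) moving@pixels else moving
  refPx <- if (is(reference, "Frame")) reference@pixels else reference
  if (!identical(dim(movPx), dim(refPx)))
    stop("moving and reference frames must share one shape")
  corners <- detectCorners(refPx, maxCorners = maxCorners,
                           margin = patchRadius)
  if (nrow(corners) < minKeypoints)
    stop(sprintf(
      "untextured scene: only %d keypoints found (need %d)",
      nrow(corners), minKeypoints))
  refPts <- NULL; movPts <- NULL
  for (i in seq_len(nrow(corners))) {
    m <- nccMatch(movPx, refPx, corners[i, ], patchRadius, searchRadius)
    if (is.null(m) || m$score < nccMin) next
    refPts <- rbind(refPts, c(corners[i, 2L], corners[i, 1L]))  # (x, y)
    movPts <- rbind(movPts, c(m$pos[2L], m$pos[1L]))
  }
  if (is.null(refPts) || nrow(refPts) < minKeypoints)
    stop(sprintf("untextured scene: only %d keypoint matches (need %d)",
                 if (is.null(refPts)) 0L else nrow(refPts), minKeypoints))
  nM <- nrow(refPts)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  bestInl <- logical(nM); bestCount <- -1L
  for (it in seq_len(ransacIter)) {
    s <- sample.int(nM, 3L)
    a <- fitAffine(movPts[s, , drop = FALSE], refPts[s, , drop = FALSE])
    if (is.null(a)) next
    pred <- cbind(movPts, 1) %*% t(a)
    res <- sqrt(rowSums((pred - refPts)^2))
    inl <- res <= inlierTol
    if (sum(inl) > bestCount) {
      bestCount <- sum(inl); bestInl <- inl
    }
  }
  if (bestCount < minKeypoints)
    stop(sprintf("alignment consensus too small: %d inliers (need %d)",
                 bestCount, minKeypoints))
  a <- fitAffine(movPts[bestInl, , drop = FALSE],
                 refPts[bestInl, , drop = FALSE])
  pred <- cbind(movPts, 1) %*% t(a)
  res <- sqrt(rowSums((pred - refPts)^2))
  inl <- res <= inlierTol
  a <- fitAffine(movPts[inl, , drop = FALSE], refPts[inl, , drop = FALSE])
  pred <- cbind(movPts[inl, , drop = FALSE], 1) %*% t(a)
  med <- stats::median(sqrt(rowSums((pred - refPts[inl, , drop = FALSE])^2)))
  affineTransform(a, nInliers = sum(inl), residual = med)
}

#' Warp an image matrix under an affine transform
#'
#' Low-level resampling: the output at reference coordinates x equals the
#' input at \code{A^{-1} x}, with bilinear interpolation. Used by
#' \code{\link{warpToReference}} and by the scene simulator to inject
#' nacelle motion.
#'
#' @param px numeric pixel matrix
#' @param transform an \linkS4class{AffineTransform}
#' @param fill \code{"na"} marks out-of-view pixels \code{NA} (an
#'   \code{"inside"} attribute carries the validity map);
#'   \code{"replicate"} clamps sampling to the edge
#' @return the warped matrix
#' @export
warpImage <- function(px, transform, fill = c("na", "replicate")) {
  fill <- match.arg(fill)
  h <- nrow(px); w <- ncol(px)
  inv <- invertTransform(transform)@coefficients
  gx <- rep(seq_len(w), each = h)    # x = col
  gy <- rep(seq_len(h), times = w)   # y = row
  sx <- inv[1L, 1L] * gx + inv[1L, 2L] * gy + inv[1L, 3L]
  sy <- inv[2L, 1L] * gx + inv[2L, 2L] * gy + inv[2L, 3L]
  inside <- sx >= 1 & sx <= w & sy >= 1 & sy <= h
  if (fill == "replicate") {
    sx <- pmin(pmax(sx, 1), w)
    sy <- pmin(pmax(sy, 1), h)
  }
  x0 <- pmin(pmax(floor(sx), 1), w - 1L); y0 <- pmin(pmax(floor(sy), 1), h - 1L)
  fx <- sx - x0; fy <- sy - y0
  idx <- function(r, c) (c - 1L) * h + r
  v <- (1 - fx) * (1 - fy) * px[idx(y0, x0)] +
    fx * (1 - fy) * px[idx(y0, x0 + 1L)] +
    (1 - fx) * fy * px[idx(y0 + 1L, x0)] +
    fx * fy * px[idx(y0 + 1L, x0 + 1L)]
  if (fill == "na") v[!inside] <- NA_real_
  out <- matrix(v, h, w)
  attr(out, "inside") <- matrix(inside, h, w)
  out
}

#' Resample a frame into reference coordinates
#'
#' Bilinear resampling under the given moving-to-reference transform.
#' Pixels whose source falls outside the moving frame's field of view (or
#' onto its masked pixels) are masked in the result and excluded from all
#' downstream statistics.
#'
#' @param frame the moving \linkS4class{Frame}
#' @param transform an \linkS4class{AffineTransform} mapping the frame onto
#'   the reference
#' @return the warped \linkS4class{Frame}
#' @export
warpToReference <- function(frame, transform) {
  warped <- warpImage(frame@pixels, transform, fill = "na")
  inside <- attr(warped, "inside")
  mask <- inside
  if (!all(frame@mask)) {
    mwarp <- warpImage(matrix(as.numeric(frame@mask), nrow(frame@mask)),
                       transform, fill = "na")
    mask <- inside & !is.na(mwarp) & mwarp > 0.999
  }
  px <- warped
  px[!mask] <- 0
  attr(px, "inside") <- NULL
  Frame(pmin(pmax(px, 0), 255), frame@timestamp, frame@channel,
        frame@frameId, mask = mask)
}
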