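## Internal numeric helpers shared across modules.

## Element-wise median across a list of equally sized numeric matrices,
## computed with a vectorized exchange-sort over the "time" axis so that no
## per-pixel R-level loop is needed. Returns a matrix of the input shape.
matrixMedian <- function(mats) {
  k <- length(mats)
  stopifnot(k >= 1L)
  if (k == 1L) return(mats[[1L]])
  cols <- lapply(mats, as.numeric)
  ## bubble network of pmin/pmax comparators: full sort across the k slots
  for (i in seq_len(k - 1L)) {
    for (j in seq_len(k - i)) {
      lo <- pmin(cols[[j]], cols[[j + 1L]])
      hi <- pmax(cols[[j]], cols[[j + 1L]])
      cols[[j]] <- lo
      cols[[j + 1L]] <- hi
    }
  }
  med <- if (k %% 2L == 1L) {
    cols[[(k + 1L) %/% 2L]]
  } else {
    (cols[[k %/% 2L]] + cols[[k %/% 2L + 1L]]) / 2
  }
  matrix(med, nrow = nrow(mats[[1L]]), ncol = ncol(mats[[1L]]))
}

## Sliding-window sum over a (2r+1)x(2r+1) box, window clipped at the image
## border, via integral images. x may contain NAs if na.zero is used.
boxSum <- function(x, r) {
  if (r == 0L) return(x)
  h <- nrow(x); w <- ncol(x)
  ## pad integral image with a leading zero row/col
  ii <- matrix(0, h + 1L, w + 1L)
  ii[-1L, -1L] <- apply(apply(x, 2L, cumsum), 1L, cumsum) |> t()
  rows <- seq_len(h); cols <- seq_len(w)
  r1 <- pmax(rows - r, 1L); r2 <- pmin(rows + r, h)
  c1 <- pmax(cols - r, 1L); c2 <- pmin(cols + r, w)
  ii[r2 + 1L, c2 + 1L, drop = FALSE] -
    ii[r1, c2 + 1L, drop = FALSE] -
    ii[r2 + 1L, c1, drop = FALSE] +
    ii[r1, c1, drop = FALSE]
}

## Half-up rounding at a fixed number of decimals (round() is round-half-even)
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Chebyshev (square) dilation of a logical matrix by radius r
dilateMask <- function(mask, r) {
  if (r <= 0L || !any(mask)) return(mask)
  m <- EBImage::dilate(matrix(as.numeric(mask), nrow(mask)),
                       EBImage::makeBrush(2L * as.integer(r) + 1L, "box"))
  m > 0.5
}

## pixel index helpers: regions carry (row, col) integer matrices
coordsToIndex <- function(coords, dim) {
  (coords[, 2L] - 1L) * dim[1L] + coords[, 1L]
}

maskToCoords <- function(mask) {
  which(mask, arr.ind = TRUE)
}
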