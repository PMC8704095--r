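## shared builders for synthetic frames and stacks

constFrame <- function(value, timestamp, channel = "LWIR", dim = c(8L, 8L),
                       id = as.integer(timestamp / 10)) {
  Frame(matrix(value, dim[1L], dim[2L]), timestamp, channel, id)
}

## stack from one scalar gray value per frame (flat frames)
flatStack <- function(values, channel = "LWIR", dim = c(8L, 8L),
                      excludeMiddle = FALSE) {
  st <- ImageStack(halfSize = length(values) %/% 2L,
                   excludeMiddle = excludeMiddle)
  for (i in seq_along(values))
    st <- pushFrame(st, constFrame(values[i], i * 10, channel, dim, i))
  st
}

## stack from a list of pixel matrices
matStack <- function(mats, channel = "LWIR", halfSize = length(mats) %/% 2L) {
  st <- ImageStack(halfSize = halfSize)
  for (i in seq_along(mats))
    st <- pushFrame(st, Frame(mats[[i]], i * 10, channel, i))
  st
}

## textured reference image for registration tests
texturedImage <- function(seed, dim = c(96L, 96L), amplitude = 20) {
  spec <- sceneSpec(width = dim[2L], height = dim[1L], nFrames = 1L,
                    seed = seed, textureAmplitude = amplitude, noiseSigma = 1)
  generateSequence(spec)$frames[[1L]]@pixels
}

## rotation + translation about the image centre, as an AffineTransform
rigidTransform <- function(dim, tx, ty, degrees) {
  th <- degrees * pi / 180
  cx <- (dim[2L] + 1) / 2
  cy <- (dim[1L] + 1) / 2
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  affineTransform(cbind(rot, c(cx, cy) - rot %*% c(cx, cy) + c(tx, ty)))
}

## loop-based SSIM oracle (independent of the package implementation)
ssimOracle <- function(x, y, c1, c2) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  vx <- 0; vy <- 0; cxy <- 0
  for (i in seq_len(n)) {
    vx <- vx + (x[i] - mx)^2
    vy <- vy + (y[i] - my)^2
    cxy <- cxy + (x[i] - mx) * (y[i] - my)
  }
  vx <- vx / n; vy <- vy / n; cxy <- cxy / n
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

## canonical nighttime drop-test scene: drop (optional) in the central
## zone, walker corridor and wind patch along the bottom edge
dropTestSpec <- function(seed, drop = TRUE) {
  set.seed(seed * 17L)
  pos <- c(sample(16:38, 1L), sample(16:48, 1L))
  sceneSpec(
    seed = seed,
    dropEvents = if (drop)
      data.frame(frame = 18, row = pos[1L], col = pos[2L], size = 2,
                 contrast = 30, tau = 300),
    walkerEvents = data.frame(startFrame = 8, endFrame = 16, startRow = 56,
                              startCol = 4, endRow = 53, endCol = 60,
                              size = 3, contrast = 25),
    windEvents = data.frame(startFrame = 1, endFrame = 40, row = 58,
                            col = 12, radius = 7, amplitude = 15))
}
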