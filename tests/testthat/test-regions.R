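mkScoreMap <- function(s, channel = "LWIR", mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(s), ncol(s))
  new("ScoreMap", scores = s, mask = mask, channel = channel)
}

test_that("a constant score map with positive offset thresholds nothing", {
  sm <- mkScoreMap(matrix(7, 40, 40))
  expect_false(any(adaptiveThreshold(sm, 15, 1)))
})

test_that("a single high pixel survives as exactly that pixel", {
  s <- matrix(0, 40, 40)
  s[20, 20] <- 50
  bin <- adaptiveThreshold(mkScoreMap(s), blockSize = 15, offset = 5)
  expect_equal(which(bin), which(s == 50))
})

test_that("local thresholding matches a sliding-window mean oracle", {
  set.seed(31)
  s <- matrix(rnorm(400, 0, 3), 20, 20)
  bs <- 5L; off <- 2
  bin <- adaptiveThreshold(mkScoreMap(s), bs, off)
  r <- (bs - 1L) %/% 2L
  for (i in seq_len(20)) for (j in seq_len(20)) {
    win <- s[max(1, i - r):min(20, i + r), max(1, j - r):min(20, j + r)]
    expect_identical(bin[i, j], s[i, j] > mean(win) + off)
  }
})

test_that("plateaus in differently shadowed halves are both detected", {
  s <- matrix(0, 40, 60)
  s[, 31:60] <- -20                 # shadowed half sits lower
  s[10:11, 10:11] <- 25             # plateau in the bright half
  s[30:31, 45:46] <- -20 + 25       # same relative elevation in the shadow
  bin <- adaptiveThreshold(mkScoreMap(s), 15, 5)
  expect_true(all(bin[10:11, 10:11]))
  expect_true(all(bin[30:31, 45:46]))
})

test_that("masked pixels are excluded from both mean and output", {
  s <- matrix(0, 20, 20)
  s[5, 5] <- 50
  mask <- matrix(TRUE, 20, 20)
  mask[5, 5] <- FALSE
  bin <- adaptiveThreshold(mkScoreMap(s, mask = mask), 7, 5)
  expect_false(any(bin))
})

test_that("invalid block sizes are rejected", {
  sm <- mkScoreMap(matrix(0, 20, 20))
  expect_error(adaptiveThreshold(sm, 4, 1), "odd")
  expect_error(adaptiveThreshold(sm, 1, 1), "odd|>= 3")
  expect_error(adaptiveThreshold(sm, 21, 1), "smaller")
})

test_that("an empty binary map yields an empty region set", {
  rs <- generateRegions(matrix(FALSE, 20, 20))
  expect_length(regions(rs), 0L)
})

test_that("near pixels merge into one region, far pixels stay separate", {
  b <- matrix(FALSE, 40, 40)
  b[20, 10] <- TRUE
  b[20, 10 + 2 * 3] <- TRUE         # within reach of dilation radius 3
  rs <- generateRegions(b, openingRadius = 0, dilateIters = 3)
  expect_length(regions(rs), 1L)
  b2 <- matrix(FALSE, 40, 40)
  b2[10, 10] <- TRUE
  b2[30, 30] <- TRUE
  rs2 <- generateRegions(b2, openingRadius = 0, dilateIters = 3)
  expect_length(regions(rs2), 2L)
})

test_that("a single-pixel object keeps its pixel as inner with an outer ring", {
  b <- matrix(FALSE, 30, 30)
  b[15, 15] <- TRUE
  rs <- generateRegions(b, openingRadius = 0, dilateIters = 3, gapIters = 1)
  r <- regions(rs)[[1]]
  expect_equal(r$inner, cbind(15L, 15L), ignore_attr = TRUE)
  expect_equal(r$area, 1L)
  expect_gt(nrow(r$outer), 0L)
  ## the gap: no outer pixel touches the inner pixel
  cheb <- pmax(abs(r$outer[, 1] - 15), abs(r$outer[, 2] - 15))
  expect_true(all(cheb >= 2))
  ## full is the Chebyshev-3 square
  expect_equal(nrow(r$full), 49L)
})

test_that("region sets keep equal inner/outer/full counts on random maps", {
  set.seed(32)
  for (rep in 1:15) {
    b <- matrix(runif(1600) < 0.04, 40, 40)
    rs <- generateRegions(b, openingRadius = 0, dilateIters = 3,
                          gapIters = 1)
    regs <- regions(rs)
    for (r in regs) {
      expect_gt(nrow(r$inner), 0L)
      expect_gt(nrow(r$full), 0L)
      ii <- paste(r$inner[, 1], r$inner[, 2])
      oo <- paste(r$outer[, 1], r$outer[, 2])
      ff <- paste(r$full[, 1], r$full[, 2])
      expect_length(intersect(ii, oo), 0L)
      expect_true(all(ii %in% ff))
      expect_true(all(oo %in% ff))
      ## inner pixels come from the thresholded map
      expect_true(all(b[r$inner]))
      ## every outer pixel is within dilateIters of some inner pixel,
      ## but never adjacent to one (gap >= 1)
      for (k in seq_len(nrow(r$outer))) {
        cheb <- pmax(abs(r$inner[, 1] - r$outer[k, 1]),
                     abs(r$inner[, 2] - r$outer[k, 2]))
        expect_lte(min(cheb), 3)
        expect_gte(min(cheb), 2)
      }
    }
    ## labels unique
    labs <- vapply(regs, function(r) r$label, numeric(1))
    expect_equal(anyDuplicated(labs), 0L)
  }
})

test_that("morphological opening removes speckle and never adds pixels", {
  b <- matrix(FALSE, 30, 30)
  b[5, 5] <- TRUE                   # lone speckle
  b[15:19, 15:19] <- TRUE           # solid 5x5 block
  rs <- generateRegions(b, openingRadius = 1, dilateIters = 2, gapIters = 1)
  regs <- regions(rs)
  expect_length(regs, 1L)
  expect_true(all(regs[[1]]$inner[, 1] >= 15))
  expect_true(all(b[regs[[1]]$inner]))
})

test_that("diagonally touching pixels form one 8-connected region", {
  b <- matrix(FALSE, 20, 20)
  b[10, 10] <- TRUE
  b[11, 11] <- TRUE
  rs <- generateRegions(b, openingRadius = 0, dilateIters = 0, gapIters = 0)
  expect_length(regions(rs), 1L)
})
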