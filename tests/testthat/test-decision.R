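## build a stack + region + score map exhibiting prescribed criterion values
presetScene <- function(area = 10L, temporal = 27, spatial = 36,
                        surround = 0.24, dim = c(24L, 24L)) {
  ## old frames: flat 50; new frames: inner at 50+temporal, outer at
  ## 50+temporal-spatial, rest 50
  innerCoords <- maskCoords <- NULL
  b <- matrix(FALSE, dim[1L], dim[2L])
  b[12, 8 + seq_len(area)] <- TRUE    # a row of `area` pixels
  rs <- generateRegions(b, openingRadius = 0, dilateIters = 2, gapIters = 1)
  r <- regions(rs)[[1]]
  newPx <- matrix(50, dim[1L], dim[2L])
  newPx[r$outer] <- 50 + temporal - spatial
  newPx[r$inner] <- 50 + temporal
  mats <- c(replicate(5, matrix(50, dim[1L], dim[2L]), simplify = FALSE),
            replicate(5, newPx, simplify = FALSE))
  st <- matStack(mats, channel = "LWIR")
  s <- matrix(surround, dim[1L], dim[2L])   # uniform |score| in the annulus
  sm <- new("ScoreMap", scores = s, mask = matrix(TRUE, dim[1L], dim[2L]),
            channel = "LWIR")
  list(region = r, stack = st, score = sm)
}

test_that("the reference thermal candidate passes all preselection criteria", {
  sc <- presetScene(area = 10L, temporal = 27, spatial = 36, surround = 0.24)
  p <- preselect(sc$region, sc$stack, sc$score,
                 preselectionThresholds("LWIR"))
  expect_true(p$pass)
  expect_equal(p$values$area, 10L)
  expect_equal(p$values$temporal, 27)
  expect_equal(p$values$spatial, 36)
  expect_equal(p$values$surround, 0.24)
})

test_that("area outside the limits is rejected on the area criterion", {
  sc <- presetScene(area = 10L)
  th <- preselectionThresholds("LWIR", areaMax = 5)
  p <- preselect(sc$region, sc$stack, sc$score, th)
  expect_false(p$pass)
  expect_equal(p$reason, "area")
})

test_that("weak discernibility is rejected with the right reason", {
  scT <- presetScene(temporal = 5, spatial = 36)
  pT <- preselect(scT$region, scT$stack, scT$score)
  expect_false(pT$pass)
  expect_match(pT$reason, "temporal")
  scS <- presetScene(temporal = 27, spatial = 5)
  pS <- preselect(scS$region, scS$stack, scS$score)
  expect_false(pS$pass)
  expect_match(pS$reason, "spatial")
})

test_that("a wind-elevated surround rejects even a well-formed candidate", {
  sc <- presetScene(surround = 4.5)   # > 2.9 mean |score| in the annulus
  p <- preselect(sc$region, sc$stack, sc$score)
  expect_false(p$pass)
  expect_equal(p$reason, "surround score")
})

test_that("ssim is exactly 1 for identical and for equal-constant inputs", {
  set.seed(41)
  x <- runif(30)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(rep(0.4, 10), rep(0.4, 10)), 1)
})

test_that("ssim agrees with a loop-based statistics oracle", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(2:200, 1)
    x <- runif(n)
    y <- runif(n)
    for (c2 in c(0, 0.01, 0.03)) {
      expect_equal(ssim(x, y, 1e-4, c2), ssimOracle(x, y, 1e-4, c2),
                   tolerance = 1e-12)
      expect_equal(ssim(x, y, 1e-4, c2), ssim(y, x, 1e-4, c2))
    }
  }
})

test_that("ssim grows with c2 when variances dominate the covariance", {
  set.seed(43)
  x <- runif(30)
  y <- runif(30)
  stopifnot(var(x) + var(y) > 2 * cov(x, y))
  s <- vapply(c(0, 0.01, 0.03), function(c2) ssim(x, y, 1e-4, c2),
              numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("ssim rejects mismatched or too-short inputs", {
  expect_error(ssim(1:3 / 3, 1:4 / 4), "length")
  expect_error(ssim(0.5, 0.5), "2 pixels")
})

test_that("sdiffSeries is elementwise 1 - ssim over the full region", {
  set.seed(44)
  mats <- replicate(10, matrix(runif(64, 0, 255), 8, 8), simplify = FALSE)
  st <- matStack(mats)
  b <- matrix(FALSE, 8, 8)
  b[4, 4] <- TRUE
  r <- regions(generateRegions(b, 0, 2, 1))[[1]]
  th <- structuralThresholds()
  sd <- sdiffSeries(r, st, th)
  expect_length(sd, 9L)
  idx <- (r$full[, 2] - 1) * 8 + r$full[, 1]
  for (i in 1:9) {
    expected <- 1 - ssim(mats[[i]][idx] / 255, mats[[i + 1]][idx] / 255,
                         th@c1, th@c2)
    expect_equal(sd[i], min(max(expected, 0), 1))
  }
  expect_true(all(sd >= 0 & sd <= 1))
})

test_that("identical frames give an all-zero SDIFF series", {
  mats <- replicate(10, matrix(rep(1:16, 4), 8, 8), simplify = FALSE)
  st <- matStack(mats)
  b <- matrix(FALSE, 8, 8); b[4, 4] <- TRUE
  r <- regions(generateRegions(b, 0, 2, 1))[[1]]
  expect_true(all(sdiffSeries(r, st) == 0))
})

test_that("a heavily masked region is refused for structural analysis", {
  st <- ImageStack(halfSize = 5L)
  for (i in 1:10) {
    m <- matrix(TRUE, 8, 8)
    if (i == 5) m[, 1:4] <- FALSE     # half the image gone in one frame
    st <- pushFrame(st, Frame(matrix(100, 8, 8), i * 10, "LWIR", i, mask = m))
  }
  b <- matrix(FALSE, 8, 8); b[4, 3] <- TRUE
  r <- regions(generateRegions(b, 0, 2, 1))[[1]]
  expect_error(sdiffSeries(r, st), "masked")
})

test_that("a clean middle spike with quiet sides is detected", {
  sdiffs <- c(0.007, 0.004, 0.004, 0.003, 0.443, 0.003, 0.005, 0.003, 0.004)
  d <- structuralDecision(sdiffs)
  expect_equal(d$verdict, "detected")
  expect_equal(d$values$middleSdiff, 0.443)
  expect_gt(d$values$sdiffQuotient, 3)
})

test_that("a uniformly low series is rejected on the middle criterion", {
  d <- structuralDecision(rep(0.001, 9))
  expect_equal(d$verdict, "rejected_structural")
  expect_equal(d$reason, "middle SDIFF")
})

test_that("restless side pairs are rejected on the side criterion", {
  sdiffs <- c(0.003, 0.2, 0.003, 0.003, 0.4, 0.25, 0.003, 0.003, 0.003)
  d <- structuralDecision(sdiffs)
  expect_equal(d$verdict, "rejected_structural")
  expect_equal(d$reason, "side SDIFF")
})

test_that("a relatively unremarkable middle fails the quotient", {
  sdiffs <- c(0.02, 0.02, 0.02, 0.02, 0.04, 0.02, 0.02, 0.02, 0.02)
  d <- structuralDecision(sdiffs)
  expect_equal(d$verdict, "rejected_structural")
  expect_equal(d$reason, "SDIFF quotient")
})

test_that("all-zero sides give an infinite quotient and pass with the middle", {
  d <- structuralDecision(c(rep(0, 4), 0.3, rep(0, 4)))
  expect_equal(d$verdict, "detected")
  expect_equal(d$values$sdiffQuotient, Inf)
})

test_that("even-length series are refused", {
  expect_error(structuralDecision(rep(0.01, 8)), "odd")
})

test_that("raising the middle SDIFF never flips detected to rejected", {
  base <- c(0.003, 0.004, 0.002, 0.003, 0.05, 0.004, 0.003, 0.002, 0.003)
  th <- structuralThresholds()
  verdicts <- vapply(seq(0.05, 0.9, by = 0.05), function(m) {
    s <- base; s[5] <- m
    structuralDecision(s, th)$verdict
  }, character(1))
  firstDetected <- match("detected", verdicts)
  expect_false(is.na(firstDetected))
  expect_true(all(verdicts[firstDetected:length(verdicts)] == "detected"))
})

test_that("evaluateCandidate assembles the full criteria record", {
  sc <- presetScene()
  ev <- evaluateCandidate(sc$region, sc$stack, sc$score)
  ## flat halves change abruptly at the transition: structural detection
  expect_equal(ev@verdict, "detected")
  expect_length(ev@sdiffSeries, 9L)
  expect_true(all(c("area", "temporal", "spatial", "surround",
                    "middleSdiff", "maxSideSdiff", "sdiffQuotient") %in%
                    names(ev@criterionValues)))
  bad <- evaluateCandidate(sc$region, sc$stack, sc$score,
                           preselectionThresholds("LWIR", areaMax = 5))
  expect_equal(bad@verdict, "rejected_preselection")
  expect_equal(bad@rejectionReason, "area")
})
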