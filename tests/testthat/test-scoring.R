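test_that("the default lookup curve honors its anchors and interpolates", {
  lut <- defaultShiftLUT()
  expect_equal(lutShift(lut, 255), 70)
  expect_equal(lutShift(lut, 0), 0)
  ## manual linear-interpolation oracle over anchors (0,0),(70,70),(255,70)
  interp <- function(d) if (d <= 70) d else 70 + (d - 70) * (70 - 70) / 185
  for (d in c(15, 35, 70, 160, 200))
    expect_equal(lutShift(lut, d), interp(d))
  expect_equal(lutShift(lut, matrix(c(10, 100), 1)), matrix(c(10, 70), 1))
  expect_error(lutShift(lut, -1), "0, 255")
  expect_error(lutShift(lut, 300), "0, 255")
})

test_that("LUT validity rejects malformed anchor sets", {
  expect_error(shiftLUT(cbind(c(0, 70, 70), c(0, 10, 70))), "increase")
  expect_error(shiftLUT(cbind(c(0, 255), c(0, 50))), "70")
  expect_error(shiftLUT(cbind(c(10, 255), c(0, 70))), "cover")
})

test_that("a constant stack scores zero everywhere", {
  st <- flatStack(rep(120, 10), channel = "VIS")
  expect_true(all(scoreVis(st)@scores == 0))
  stL <- flatStack(rep(120, 10), channel = "LWIR")
  expect_true(all(scoreLwir(stL)@scores == 0))
})

test_that("an ideal step scores the lookup of its magnitude, no penalty", {
  st <- flatStack(c(rep(120, 5), rep(90, 5)), channel = "VIS")
  sm <- scoreVis(st)
  expect_true(all(sm@scores == lutShift(defaultShiftLUT(), 30)))
  expect_true(all(sm@scores == 30))
})

test_that("alternating gray values match a loop oracle and score poorly", {
  vals <- rep(c(120, 90), 5)          # moving-grass flicker
  st <- flatStack(vals, channel = "VIS")
  alpha <- 1
  N <- 5L
  ## direct per-index evaluation of the score rule
  lut <- function(d) lutShift(defaultShiftLUT(), d)
  step <- abs(vals[N + 1L] - vals[N])
  penNew <- sum(abs(diff(vals[(N + 1L):(2L * N)]))) / (N - 1L)
  penOld <- sum(abs(diff(vals[1L:N]))) / (N - 1L)
  expected <- lut(step) - alpha * penNew - alpha * penOld
  sm <- scoreVis(st, scoringConfig("VIS", alpha = alpha))
  expect_true(all(sm@scores == expected))
  expect_lt(expected, 30)             # far below the ideal-step score
})

test_that("alpha weights the penalties linearly", {
  vals <- rep(c(120, 90), 5)
  st <- flatStack(vals, channel = "VIS")
  s0 <- scoreVis(st, scoringConfig("VIS", alpha = 0))@scores[1, 1]
  s2 <- scoreVis(st, scoringConfig("VIS", alpha = 2))@scores[1, 1]
  expect_equal(s0, 30)
  expect_equal(s2, 30 - 2 * 60)
})

test_that("the LWIR score is the difference of the half medians", {
  st <- flatStack(c(10, 10, 11, 10, 10, 40, 41, 40, 40, 39))
  expect_true(all(scoreLwir(st)@scores == 30))
  ## transient hot outlier in the old half is ignored by the median
  st2 <- flatStack(c(10, 10, 80, 10, 10, 10, 10, 10, 10, 10))
  expect_true(all(scoreLwir(st2)@scores == 0))
})

test_that("random stacks agree with a sort-based median oracle", {
  set.seed(21)
  for (rep in 1:20) {
    vals <- sample(0:255, 10, replace = TRUE)
    st <- flatStack(vals)
    med <- function(v) { s <- sort(v); (s[3L]) }   # middle of 5
    expected <- med(vals[6:10]) - med(vals[1:5])
    expect_true(all(scoreLwir(st)@scores == expected))
  }
})

test_that("the LWIR score is antisymmetric under swapping the halves", {
  set.seed(22)
  for (rep in 1:10) {
    vals <- sample(0:255, 10, replace = TRUE)
    fwd <- scoreLwir(flatStack(vals))@scores[1, 1]
    rev <- scoreLwir(flatStack(c(vals[6:10], vals[1:5])))@scores[1, 1]
    expect_equal(fwd, -rev)
  }
})

test_that("a single-frame spike leaves the median score but cuts the VIS score", {
  base <- c(rep(120, 5), rep(90, 5))
  spiked <- base
  spiked[3] <- 200
  expect_equal(scoreLwir(flatStack(spiked))@scores[1, 1],
               scoreLwir(flatStack(base))@scores[1, 1])
  sVis <- scoreVis(flatStack(base, channel = "VIS"))@scores[1, 1]
  sVisSpiked <- scoreVis(flatStack(spiked, channel = "VIS"))@scores[1, 1]
  expect_lt(sVisSpiked, sVis)
})

test_that("masked pixels propagate into the score map", {
  mats <- replicate(10, matrix(100, 8, 8), simplify = FALSE)
  st <- ImageStack(halfSize = 5L)
  for (i in 1:10) {
    m <- matrix(TRUE, 8, 8)
    if (i == 4) m[2, 3] <- FALSE
    st <- pushFrame(st, Frame(mats[[i]], i * 10, "LWIR", i, mask = m))
  }
  sm <- scoreLwir(st)
  expect_true(is.na(sm@scores[2, 3]))
  expect_false(sm@mask[2, 3])
  expect_equal(sum(is.na(sm@scores)), 1L)
})
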