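test_that("the same spec and seed render bit-identical frames", {
  spec <- dropTestSpec(5)
  a <- generateSequence(spec)
  b <- generateSequence(spec)
  for (i in seq_along(a$frames))
    expect_identical(a$frames[[i]]@pixels, b$frames[[i]]@pixels)
  expect_identical(a$truth, b$truth)
})

test_that("no events and no noise give a perfectly static sequence", {
  spec <- sceneSpec(nFrames = 12L, noiseSigma = 0)
  g <- generateSequence(spec)
  for (f in g$frames[-1])
    expect_identical(f@pixels, g$frames[[1]]@pixels)
  ## and the downstream score map is identically zero
  st <- ImageStack(halfSize = 5L)
  for (i in 1:10) st <- pushFrame(st, g$frames[[i]])
  expect_true(all(scoreLwir(st)@scores == 0))
})

test_that("a drop appears at its frame with its contrast and persists", {
  spec <- sceneSpec(noiseSigma = 0,
                    dropEvents = data.frame(frame = 10, row = 30, col = 30,
                                            size = 1, contrast = 30,
                                            tau = 300))
  g <- generateSequence(spec)
  before <- g$frames[[9]]@pixels[30, 30]
  at <- g$frames[[10]]@pixels[30, 30]
  expect_equal(at - before, 30, tolerance = 0.51)   # quantization
  ## persists to the end, decaying per the cooling law
  for (t in c(15, 25, 40)) {
    expected <- coolingCurve(30, 300, (t - 10) * 10)
    expect_equal(g$frames[[t]]@pixels[30, 30] - before, expected,
                 tolerance = 0.51)
  }
})

test_that("VIS drops darken instead of warming and do not cool", {
  spec <- sceneSpec(channel = "VIS", noiseSigma = 0,
                    dropEvents = data.frame(frame = 10, row = 30, col = 30,
                                            size = 1, contrast = 30,
                                            tau = 300))
  g <- generateSequence(spec)
  before <- g$frames[[9]]@pixels[30, 30]
  expect_equal(g$frames[[10]]@pixels[30, 30] - before, -30, tolerance = 0.51)
  expect_equal(g$frames[[40]]@pixels[30, 30] - before, -30, tolerance = 0.51)
})

test_that("the cooling curve follows its closed form", {
  expect_equal(coolingCurve(30, 300, 0), 30)
  expect_equal(coolingCurve(30, 300, 300), 30 / exp(1))
  expect_equal(coolingCurve(30, 300, 300), 11.0364, tolerance = 1e-4)
  expect_error(coolingCurve(30, 0, 10), "tau")
  expect_error(coolingCurve(30, -5, 10), "tau")
  expect_error(coolingCurve(30, 300, -1), "non-negative")
})

test_that("overlapping drop footprints are refused", {
  expect_error(
    sceneSpec(dropEvents = data.frame(frame = c(5, 10), row = c(30, 29),
                                      col = c(30, 29), size = c(2, 2),
                                      contrast = 30, tau = 300)),
    "overlap")
})

test_that("event frames outside the sequence are refused", {
  expect_error(
    sceneSpec(nFrames = 20L,
              dropEvents = data.frame(frame = 25, row = 30, col = 30,
                                      size = 1, contrast = 30, tau = 300)),
    "outside")
})

test_that("injected nacelle jitter is recovered by registration", {
  spec <- sceneSpec(width = 96L, height = 96L, nFrames = 4L,
                    textureAmplitude = 20, jitterSigmaPx = 2,
                    jitterSigmaDeg = 0.5, seed = 9)
  g <- generateSequence(spec)
  expect_length(g$transforms, 4L)
  corners <- rbind(c(1, 1), c(1, 96), c(96, 1), c(96, 96))
  ## frame 1 is itself jittered; align frames 2..4 onto it and compare
  ## with the composed truth
  for (i in 2:4) {
    est <- estimateAlignment(g$frames[[i]], g$frames[[1]], seed = i)
    truth <- composeTransforms(invertTransform(g$transforms[[1]]),
                               g$transforms[[i]])
    err <- sqrt(rowSums((transformPoints(est, corners) -
                           transformPoints(truth, corners))^2))
    expect_lt(max(err), 1)
  }
})

test_that("walkers are transient: present on the path, gone afterwards", {
  spec <- sceneSpec(noiseSigma = 0,
                    walkerEvents = data.frame(startFrame = 10, endFrame = 14,
                                              startRow = 32, startCol = 10,
                                              endRow = 32, endCol = 50,
                                              size = 1, contrast = 25))
  g <- generateSequence(spec)
  expect_equal(g$frames[[10]]@pixels[32, 10] - g$frames[[9]]@pixels[32, 10],
               25, tolerance = 0.51)
  expect_equal(g$frames[[20]]@pixels[32, 10], g$frames[[9]]@pixels[32, 10],
               tolerance = 0.51)
})

test_that("ground truth carries one record per specified event", {
  spec <- dropTestSpec(3)
  g <- generateSequence(spec)
  expect_equal(sum(g$truth$type == "drop"), 1L)
  expect_equal(sum(g$truth$type == "walker"), 1L)
  expect_equal(sum(g$truth$type == "wind"), 1L)
  d <- g$truth[g$truth$type == "drop", ]
  expect_equal(d$time, d$frame * 10)
})
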