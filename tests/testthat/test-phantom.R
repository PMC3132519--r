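# Phantom generator: ground-truth consistency, determinism, degradation
# forward models.

test_that("noiseless two-level phantom is exactly reproduced by midpoint thresholding", {
  cfg <- noiselessConfig(2L)
  ph <- generateMonolayerPhantom(cfg)
  expect_length(unique(as.vector(ph$image)), 2L)
  mid <- (cfg@boundaryMean + cfg@backgroundMean) / 2
  expect_identical(thresholdMask(ph$image, mid), ph$mask)
  expect_equal(accuracy(confusionCounts(thresholdMask(ph$image, mid), ph$mask)),
               100)
})

test_that("phantom generation is deterministic in (config, seed)", {
  a <- generateMonolayerPhantom(standardConfig(7L))
  b <- generateMonolayerPhantom(standardConfig(7L))
  c <- generateMonolayerPhantom(standardConfig(8L))
  expect_identical(a, b)
  expect_false(identical(a$image, c$image))
})

test_that("boundary-pixel fraction is plausible for a 50-cell 256x256 mosaic", {
  fracs <- vapply(1:20, function(s) {
    ph <- generateMonolayerPhantom(
      phantomConfig(width = 256L, height = 256L, nCells = 50L, seed = s))
    mean(ph$mask)
  }, numeric(1))
  expect_true(all(fracs > 0.02 & fracs < 0.30))
})

test_that("degenerate configs are rejected with clear messages", {
  expect_error(phantomConfig(nCells = 1L), "nCells")
  expect_error(phantomConfig(boundaryMean = 0.5, backgroundMean = 0.5,
                             noiseSigma = 0), "degenerate")
  expect_error(phantomConfig(width = 8L), "width")
  expect_error(phantomConfig(gapFraction = 1), "gapFraction")
})

test_that("illumination trend follows the quadratic forward model", {
  img <- matrix(0.5, 32, 48)
  expect_identical(applyIllumination(img, rep(0, 6)), img)
  expect_equal(applyIllumination(img, c(0.1, 0, 0, 0, 0, 0)),
               matrix(0.6, 32, 48))
  # linear-in-x term: left column at x = -1, right column at x = +1
  out <- applyIllumination(img, c(0, 0.2, 0, 0, 0, 0))
  expect_equal(out[1, 48] - out[1, 1], 0.4)
  expect_equal(unname(out[, 24] - out[, 25])[1],
               -0.4 / 47, tolerance = 1e-12)
  expect_error(applyIllumination(img, c(Inf, 0, 0, 0, 0, 0)), "finite")
})

test_that("montage seam shifts exactly the right-hand side", {
  img <- matrix(0.5, 20, 40)
  expect_identical(applyMontageSeam(img, 10L, 0), img)
  out <- applyMontageSeam(img, 21L, 0.1)
  expect_equal(unique(as.vector(out[, 1:20])), 0.5)
  expect_equal(unique(as.vector(out[, 21:40])), 0.6)
  expect_equal(mean(out[, 21:40]) - mean(out[, 1:20]), 0.1)
  expect_error(applyMontageSeam(img, 1L, 0.1), "out of range")
  expect_error(applyMontageSeam(img, 41L, 0.1), "out of range")
})

test_that("training patches contain both classes and the full-size patch is the input", {
  ph <- generateMonolayerPhantom(standardConfig(5L))
  patch <- sampleTrainingPatch(ph$image, ph$mask, 62L, seed = 1L)
  expect_identical(dim(patch$image), c(62L, 62L))
  expect_length(patch$mask, 3844L)
  full <- sampleTrainingPatch(ph$image, ph$mask, 128L)
  expect_identical(full$image, ph$image)
  small <- generateMonolayerPhantom(
    phantomConfig(width = 64L, height = 64L, nCells = 20L, seed = 2L))
  for (s in 1:50) {
    p <- sampleTrainingPatch(small$image, small$mask, 16L, seed = s)
    expect_true(any(p$mask == 1L) && any(p$mask == 0L))
  }
  empty <- matrix(0L, 64, 64)
  expect_error(sampleTrainingPatch(small$image, empty, 16L, seed = 1L),
               "both classes")
})

test_that("speckle pixels are isolated from the true boundary network", {
  ph <- generateMonolayerPhantom(
    phantomConfig(noiseSigma = 0, gapFraction = 0, speckleDensity = 2e-3,
                  illumCoeffs = rep(0, 6), seed = 9L))
  speckles <- which(ph$image < 0.4 & ph$mask == 0L)
  expect_gt(length(speckles), 0)
  near <- endoseg:::dilate1(ph$mask == 1L)
  expect_true(all(!near[speckles]))
})

test_that("histogram overlap of the class conditionals grows with noise", {
  ov <- vapply(c(0.02, 0.08, 0.15), function(sig) {
    mean(vapply(1:5, function(s) {
      ph <- generateMonolayerPhantom(
        phantomConfig(noiseSigma = sig, seed = s))
      histogramOverlap(fitIntensityMixture(ph$image, ph$mask))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ov) > 0))
})
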