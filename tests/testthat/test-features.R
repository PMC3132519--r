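# Orientation-dominance field, 3x3 patches, patch statistics, the 33-column
# feature matrix and its normalisation contract.

test_that("orientation field vanishes on constant images and bounds its magnitude", {
  f <- orientationDominance(matrix(0.5, 32, 32))
  expect_lt(max(sqrt(f@v1^2 + f@v2^2)), 1e-12)
  ph <- generateMonolayerPhantom(standardConfig(4L))
  fp <- orientationDominance(ph$image)
  expect_true(all(fp@v1^2 + fp@v2^2 <= 1 + 1e-9))
  expect_error(orientationDominance(ph$image, derivScale = 0), "derivScale")
})

test_that("dominant orientation recovers dark-line angles modulo 180 degrees", {
  lineImage <- function(angleDeg) {
    img <- matrix(0.6, 65, 65)
    th <- angleDeg * pi / 180
    for (t in seq(-45, 45, by = 0.25)) {
      r <- round(33 + t * sin(th)); c <- round(33 + t * cos(th))
      if (r >= 1 && r <= 65 && c >= 1 && c <= 65) img[r, c] <- 0.2
    }
    img
  }
  for (angle in c(0, 45, 90)) {
    f <- orientationDominance(lineImage(angle))
    v1 <- f@v1[33, 33]; v2 <- f@v2[33, 33]
    expect_gt(sqrt(v1^2 + v2^2), 0.5)
    rec <- (atan2(v2, v1) / 2 * 180 / pi) %% 180
    delta <- min(abs(rec - angle), 180 - abs(rec - angle))
    expect_lt(delta, 5)
  }
})

test_that("orientation features are quasi-invariant to a quadratic trend, intensities are not", {
  ph <- generateMonolayerPhantom(
    phantomConfig(illumCoeffs = rep(0, 6), seed = 5L))
  trend <- c(0, 0.01, 0.008, 0.006, 0, 0.005)
  shaded <- applyIllumination(ph$image, trend)
  fm0 <- featureValues(buildFeatureMatrix(ph$image))
  fm1 <- featureValues(buildFeatureMatrix(shaded))
  rms <- function(m) sqrt(mean(m^2))
  orientChange <- rms(fm1[, 10:27] - fm0[, 10:27]) / rms(fm0[, 10:27])
  intensChange <- rms(fm1[, 1:9] - fm0[, 1:9]) / rms(fm0[, 1:9] - mean(fm0[, 1:9]))
  expect_lt(orientChange, 0.01)
  expect_gt(intensChange, 5 * orientChange)
})

test_that("patch extraction follows row-major order with reflect padding", {
  img <- matrix(0.3, 16, 16)
  expect_equal(patchIntensities(img, 8, 8), rep(0.3, 9))
  # direct-indexing oracle on a 9x9 image holding 1..81 (row-major layout)
  m <- matrix(1:81 / 81, 9, 9, byrow = TRUE)
  expect_equal(patchIntensities(m, 5, 5),
               as.vector(t(m[4:6, 4:6])))
  # corner: symmetric reflection duplicates the first row/column
  corner <- patchIntensities(m, 1, 1)
  expect_equal(corner, c(m[1, 1], m[1, 1], m[1, 2],
                         m[1, 1], m[1, 1], m[1, 2],
                         m[2, 1], m[2, 1], m[2, 2]))
  expect_error(patchIntensities(m, 0, 1), "out of bounds")
})

test_that("patch statistics match brute-force arithmetic", {
  expect_equal(unname(patchStatistics(rep(0.4, 9))),
               c(0.4, 0, 9 * 0.4^2, 0, 0, 0))
  expect_equal(unname(patchStatistics(0:8)),
               c(4, 8, 204, 60 / 9, 0, 708 / 9))
  set.seed(1)
  for (i in 1:25) {
    p <- runif(9)
    s <- patchStatistics(p)
    mu <- mean(p)
    expect_equal(unname(s), c(median(p), max(p) - min(p), sum(p^2),
                              mean((p - mu)^2), mean((p - mu)^3),
                              mean((p - mu)^4)))
    expect_gte(s[["M2"]], 0)
    expect_gte(s[["M4"]], s[["M2"]]^2)
    expect_gte(s[["Range"]], 0)
  }
})

test_that("feature matrix has the 9 + 18 + 6 column layout and consistent statistics", {
  ph <- generateMonolayerPhantom(standardConfig(6L))
  patch <- sampleTrainingPatch(ph$image, ph$mask, 62L, seed = 3L)
  fm <- buildFeatureMatrix(patch$image)
  v <- featureValues(fm)
  expect_identical(dim(v), c(3844L, 33L))
  expect_identical(colnames(v), featureNames33())
  expect_identical(featureGroups(),
                   c(rep("intensity", 9), rep("orientation", 18),
                     rep("statistic", 6)))
  # per-row oracle: statistics columns recomputed from the intensity columns
  for (k in c(1L, 500L, 1961L, 3844L))
    expect_equal(unname(v[k, 28:33]), unname(patchStatistics(v[k, 1:9])))
  # centre column is the pixel itself, in row-major scan order
  expect_equal(v[, 5], as.vector(t(patch$image)))
  # subset request matches the corresponding full rows
  pix <- cbind(row = c(1L, 10L, 62L), col = c(1L, 20L, 62L))
  sub <- featureValues(buildFeatureMatrix(patch$image, pixels = pix))
  idx <- (pix[, 1] - 1L) * 62L + pix[, 2]
  expect_equal(sub, v[idx, , drop = FALSE])
  expect_error(buildFeatureMatrix(patch$image,
                                  pixels = cbind(70L, 1L)), "out of bounds")
})

test_that("feature extraction is deterministic", {
  ph <- generateMonolayerPhantom(standardConfig(8L))
  a <- buildFeatureMatrix(ph$image)
  b <- buildFeatureMatrix(ph$image)
  expect_identical(featureValues(a), featureValues(b))
})

test_that("normalisation centres and scales every training column", {
  ph <- generateMonolayerPhantom(standardConfig(9L))
  patch <- sampleTrainingPatch(ph$image, ph$mask, 40L, seed = 2L)
  fm <- normalizeFeatures(buildFeatureMatrix(patch$image))
  z <- featureValues(fm)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  popSd <- sqrt(colMeans(sweep(z, 2, colMeans(z))^2))
  expect_lt(max(abs(popSd - 1)), 1e-9)
  expect_true(fm@normalized)
})

test_that("training statistics replay exactly on test data and invert", {
  ph <- generateMonolayerPhantom(standardConfig(10L))
  tr <- sampleTrainingPatch(ph$image, ph$mask, 40L, seed = 1L)
  te <- sampleTrainingPatch(ph$image, ph$mask, 40L, seed = 9L)
  fmTr <- normalizeFeatures(buildFeatureMatrix(tr$image))
  raw <- buildFeatureMatrix(te$image)
  fmTe <- normalizeFeatures(raw, featureStats(fmTr))
  st <- featureStats(fmTr)
  # round trip to 1e-12
  back <- sweep(sweep(featureValues(fmTe), 2, st$scale, "*"), 2,
                st$center, "+")
  expect_equal(back, featureValues(raw), tolerance = 1e-12)
  # identical copies transform identically; re-normalising is refused
  fmTe2 <- normalizeFeatures(buildFeatureMatrix(te$image), featureStats(fmTr))
  expect_identical(featureValues(fmTe), featureValues(fmTe2))
  expect_error(normalizeFeatures(fmTe), "already normalised")
})

test_that("zero-variance columns are centred only, with a warning", {
  flat <- matrix(0.5, 20, 20)
  fm <- buildFeatureMatrix(flat)
  expect_warning(nz <- normalizeFeatures(fm), "zero-variance")
  expect_true(any(nz@constant))
  expect_true(all(nz@scale[nz@constant] == 1))
  expect_lt(max(abs(featureValues(nz))), 1e-12)
})
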