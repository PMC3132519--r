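# Discretisation, mutual information and the greedy mRMR ranking.

test_that("three-level discretisation matches normal-CDF proportions", {
  set.seed(31)
  x <- embed33(matrix(rnorm(60000), ncol = 1))
  fm <- rawFeatureMatrix(x)
  d <- discretizeFeatures(fm)
  props <- as.vector(table(d[, 1]) / nrow(d))
  # P(|Z| < 0.5) = 0.3829; tails 0.3085 each
  expect_equal(props, c(0.3085, 0.3829, 0.3085), tolerance = 0.02)
  # constant column collapses to a single level
  expect_identical(unique(d[, 2]), 2L)
  # monotone transform preserving bin membership leaves levels unchanged
  y <- x; y[, 1] <- x[, 1]^3
  # cube preserves order; re-discretising the ranks of a shared grid differs,
  # but scaling by a positive constant must not change membership
  z <- x; z[, 1] <- 3.7 * x[, 1]
  expect_identical(discretizeFeatures(rawFeatureMatrix(z))[, 1], d[, 1])
})

test_that("mutual information matches closed-form and brute-force values", {
  expect_equal(mutualInformation(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  # constructed product table: exactly independent
  x <- rep(c(0, 0, 1, 1), 25)
  y <- rep(c(0, 1, 0, 1), 25)
  expect_equal(mutualInformation(x, y), 0)
  # joint counts [[2,1],[1,2]], n = 6: brute-force four-cell summation
  xj <- c(0, 0, 0, 1, 1, 1)
  yj <- c(0, 0, 1, 0, 1, 1)
  pj <- c(2, 1, 1, 2) / 6
  marg <- c(0.5 * 0.5, 0.5 * 0.5, 0.5 * 0.5, 0.5 * 0.5)
  expect_equal(mutualInformation(xj, yj), sum(pj * log2(pj / marg)))
  expect_error(mutualInformation(1:3, 1:4), "equal length")
})

test_that("mRMR ranks a perfect predictor first and a duplicate behind informative features", {
  set.seed(32)
  n <- 400L
  labels <- rep(c(0L, 1L), n / 2)
  x <- matrix(sample(1:3, n * 33, replace = TRUE), n, 33)
  x[, 7] <- labels + 1L                      # identical to the labels
  x[, 20] <- x[, 7]                          # exact duplicate of the top pick
  rk <- mrmrRank(x, labels)
  ord <- rankedFeatures(rk)
  expect_identical(ord[1], 7L)
  expect_identical(sort(ord), 1:33)
  # the duplicate never displaces its original, shares its relevance, and is
  # picked while carrying maximal redundancy with the already-selected set
  expect_gt(match(20L, ord), match(7L, ord))
  k20 <- match(20L, ord)
  expect_equal(rk@relevance[k20], rk@relevance[1])
  expect_gte(rk@redundancy[k20], max(rk@redundancy[-k20]))
  # first pick equals the argmax of single-feature MI (oracle)
  mi <- vapply(1:33, function(j) mutualInformation(x[, j], labels), numeric(1))
  expect_identical(ord[1], which.max(mi))
  expect_equal(rk@relevance[1], max(mi))
  expect_error(mrmrRank(x, labels, K = 0L), "K")
})

test_that("mRMR on phantom features returns a full 33-permutation with finite scores", {
  ph <- generateMonolayerPhantom(standardConfig(16L))
  patch <- sampleTrainingPatch(ph$image, ph$mask, 40L, seed = 5L)
  fm <- normalizeFeatures(buildFeatureMatrix(patch$image))
  d <- discretizeFeatures(fm)
  rk <- mrmrRank(d, rowMajorLabels(patch$mask))
  expect_identical(sort(rankedFeatures(rk)), 1:33)
  expect_true(all(is.finite(rk@relevance)))
  expect_true(all(is.finite(rk@redundancy)))
  mi <- vapply(1:33, function(j)
    mutualInformation(d[, j], rowMajorLabels(patch$mask)), numeric(1))
  expect_identical(rankedFeatures(rk)[1], which.max(mi))
})

test_that("grouped relevance counts and the whole-property inclusion rule behave", {
  rk <- new("FeatureRanking", order = c(1:9, 10:33), relevance = rep(1, 33),
            redundancy = rep(0, 33), group = featureGroups()[c(1:9, 10:33)])
  g9 <- groupedRelevance(rk, K = 9L)
  expect_identical(g9$topK[g9$group == "intensity"], 9L)
  expect_true(g9$flagged[g9$group == "intensity"])
  g33 <- groupedRelevance(rk, K = 33L)
  expect_identical(g33$topK, c(9L, 18L, 6L))
  expect_identical(g33$size, c(9L, 18L, 6L))
  expect_error(groupedRelevance(rk, K = 40L), "exceeds")
})

test_that("patch-based properties dominate the top of phantom rankings", {
  flagged <- vapply(1:5, function(s) {
    ph <- generateMonolayerPhantom(standardConfig(s + 50L))
    patch <- sampleTrainingPatch(ph$image, ph$mask, 40L, seed = s)
    fm <- normalizeFeatures(buildFeatureMatrix(patch$image))
    rk <- mrmrRank(discretizeFeatures(fm), rowMajorLabels(patch$mask))
    top <- featureGroups()[rankedFeatures(rk)[1:10]]
    sum(top %in% c("intensity", "orientation", "statistic")[1:2])
  }, numeric(1))
  # intensity + orientation features occupy most top-10 slots on average
  expect_gt(mean(flagged), 5)
})
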