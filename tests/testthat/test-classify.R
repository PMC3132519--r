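# SVM training, prediction, model selection and the kernel/gamma sweep.

test_that("a linearly separable toy is fit perfectly by the linear kernel", {
  set.seed(3)
  n <- 60L
  # classes separated by a clear margin along the first coordinate
  x2 <- cbind(c(runif(n, -3, -1), runif(n, 1, 3)), rnorm(2 * n))
  labels <- rep(c(0L, 1L), each = n)
  fm <- suppressWarnings(normalizeFeatures(rawFeatureMatrix(embed33(x2))))
  for (C in c(1, 10)) {
    model <- trainBoundarySvm(fm, labels, svmConfig(kernel = "linear", C = C))
    expect_identical(endoseg:::predictLabels(model, fm), labels)
  }
})

test_that("training validates its inputs", {
  set.seed(4)
  fm <- suppressWarnings(
    normalizeFeatures(rawFeatureMatrix(embed33(matrix(rnorm(40), 20, 2)))))
  expect_error(trainBoundarySvm(fm, rep(0L, 20)), "both classes")
  expect_error(trainBoundarySvm(fm, rep(c(0L, 1L), 5)), "length")
  raw <- rawFeatureMatrix(embed33(matrix(rnorm(40), 20, 2)))
  expect_error(trainBoundarySvm(raw, rep(c(0L, 1L), 10)), "normalised")
})

test_that("default RBF operating point trains on a 62x62 patch and predicts aligned masks", {
  model <- standardModel()
  expect_gt(nSupportVectors(model), 0L)
  expect_identical(model@config@kernel, "rbf")
  expect_equal(model@config@cost, 1)
  expect_equal(model@config@gamma, 0.14)
  ph <- generateMonolayerPhantom(
    phantomConfig(width = 96L, height = 64L, nCells = 30L, seed = 31L))
  pred <- predictMask(model, ph$image)
  expect_identical(dim(pred), dim(ph$image))
  expect_true(all(pred %in% c(0L, 1L)))
})

test_that("training twice on identical inputs yields identical predictions", {
  ph <- generateMonolayerPhantom(standardConfig(13L))
  patch <- sampleTrainingPatch(ph$image, ph$mask, 40L, seed = 2L)
  fm <- normalizeFeatures(buildFeatureMatrix(patch$image))
  labels <- rowMajorLabels(patch$mask)
  m1 <- trainBoundarySvm(fm, labels)
  m2 <- trainBoundarySvm(fm, labels)
  held <- generateMonolayerPhantom(
    phantomConfig(width = 64L, height = 64L, nCells = 20L, seed = 77L))
  expect_identical(predictMask(m1, held$image), predictMask(m2, held$image))
})

test_that("grid search returns the best cross-validated configuration", {
  set.seed(5)
  n <- 40L
  x2 <- cbind(c(runif(n, -3, -1), runif(n, 1, 3)), rnorm(2 * n))
  labels <- rep(c(0L, 1L), each = n)
  fm <- suppressWarnings(normalizeFeatures(rawFeatureMatrix(embed33(x2))))
  single <- gridSearchCV(fm, labels, cExponents = 0, gammas = 0.14,
                         folds = 3L)
  expect_equal(single$best@cost, 1)
  expect_equal(single$best@gamma, 0.14)
  expect_identical(nrow(single$table), 1L)
  grid <- gridSearchCV(fm, labels, cExponents = c(-2, 0, 2),
                       gammas = c(0.05, 0.14), folds = 3L)
  bestAcc <- grid$table$cvAccuracy[grid$table$C == grid$best@cost &
                                   grid$table$gamma == grid$best@gamma]
  expect_true(all(bestAcc >= grid$table$cvAccuracy))
  expect_equal(max(grid$table$cvAccuracy), 100)
  expect_error(gridSearchCV(fm, labels, cExponents = numeric(0),
                            gammas = numeric(0)), "empty")
})

test_that("gamma sweep is consistent with direct training and constant for linear", {
  ph <- generateMonolayerPhantom(standardConfig(14L))
  patch <- sampleTrainingPatch(ph$image, ph$mask, 40L, seed = 4L)
  fm <- normalizeFeatures(buildFeatureMatrix(patch$image))
  labels <- rowMajorLabels(patch$mask)
  test1 <- generateMonolayerPhantom(
    phantomConfig(width = 64L, height = 64L, nCells = 20L, seed = 55L))
  sweep <- gammaSweep(fm, labels, list(test1),
                      kernels = c("rbf", "linear"),
                      gammas = c(0.07, 0.14))
  expect_identical(names(sweep), c("gamma", "rbf", "linear"))
  expect_equal(sweep$linear[1], sweep$linear[2])
  direct <- trainBoundarySvm(fm, labels,
                             svmConfig(kernel = "rbf", C = 1, gamma = 0.14))
  directAcc <- accuracy(confusionCounts(predictMask(direct, test1$image),
                                        test1$mask))
  expect_equal(sweep$rbf[sweep$gamma == 0.14], directAcc)
})

test_that("trained models beat the majority-class baseline across boundary fractions", {
  model <- standardModel()
  for (s in c(41L, 42L)) {
    ph <- generateMonolayerPhantom(standardConfig(s))
    maj <- 100 * max(mean(ph$mask), 1 - mean(ph$mask))
    acc <- accuracy(confusionCounts(predictMask(model, ph$image), ph$mask))
    expect_gt(acc, maj)
  }
})
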