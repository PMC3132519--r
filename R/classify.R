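# Per-pixel SVM boundary classification: training on normalised 33-D feature
# vectors, whole-image prediction, stratified grid-search model selection and
# the kernel/gamma sweep used to compare kernels.

#' @importFrom e1071 svm
NULL

#' Create an SVM configuration
#'
#' The defaults are the published operating point for this problem: RBF
#' kernel, C = 1, gamma = 0.14, with 5-fold cross-validation for model
#' selection.
#'
#' @param kernel one of "rbf", "sigmoid", "polynomial", "linear".
#' @param C cost parameter (> 0).
#' @param gamma kernel width (> 0 where the kernel uses it; ignored by the
#'   linear kernel).
#' @param cvFolds cross-validation folds (>= 2).
#' @return an [SvmConfig-class].
#' @export
svmConfig <- function(kernel = "rbf", C = 1, gamma = 0.14, cvFolds = 5L) {
  new("SvmConfig", kernel = as.character(kernel), cost = as.numeric(C),
      gamma = as.numeric(gamma), cvFolds = as.integer(cvFolds))
}

e1071Kernel <- function(kernel) {
  switch(kernel, rbf = "radial", sigmoid = "sigmoid",
         polynomial = "polynomial", linear = "linear",
         stop("unknown kernel: ", kernel))
}

#' Train the per-pixel boundary SVM
#'
#' Fits a two-class SVM (libsvm via e1071) on normalised feature vectors.
#' Label convention: 1 = boundary, 0 = background. The solver tolerance is
#' fixed (1e-3) and the input is deterministic, so training twice on the same
#' data yields the same decision function. The training normalisation
#' statistics are embedded in the returned model so [predictMask()] can
#' replay them verbatim on new images.
#'
#' @param features a normalised [FeatureMatrix-class].
#' @param labels 0/1 vector, one per feature row; both classes required.
#' @param config an [SvmConfig-class].
#' @param fieldParams orientation-field parameters used when the model
#'   extracts features itself (list: derivScale, intScale, eps).
#' @return a [TrainedModel-class].
#' @export
trainBoundarySvm <- function(features, labels, config = svmConfig(),
                             fieldParams = list(derivScale = 1.0,
                                                intScale = 2.0, eps = 1e-6)) {
  stopifnot(is(features, "FeatureMatrix"), is(config, "SvmConfig"))
  validObject(config)
  if (!features@normalized)
    stop("features must be normalised before training")
  x <- features@values
  labels <- as.integer(labels)
  if (length(labels) != nrow(x))
    stop("labels length must equal the number of feature rows")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the training labels")
  if (any(!is.finite(x))) stop("features contain non-finite values")
  fit <- e1071::svm(x = x, y = factor(labels, levels = c(0L, 1L)),
                    kernel = e1071Kernel(config@kernel),
                    cost = config@cost, gamma = config@gamma,
                    scale = FALSE, tolerance = 1e-3, shrinking = TRUE)
  new("TrainedModel", fit = fit, config = config,
      center = features@center, scale = features@scale,
      constant = features@constant, fieldParams = fieldParams,
      nSupportVectors = as.integer(fit$tot.nSV))
}

# Predict 0/1 labels for a normalised feature matrix.
predictLabels <- function(model, features) {
  stopifnot(is(model, "TrainedModel"), is(features, "FeatureMatrix"))
  if (ncol(features@values) != 33L)
    stop("model requires a 33-column feature matrix")
  as.integer(as.character(predict(model@fit, features@values)))
}

#' Segment an image with a trained model
#'
#' Extracts the 33-dimensional feature vector of every pixel (orientation
#' field at the parameters stored in the model), applies the stored training
#' normalisation, classifies, and reshapes the labels into a boundary mask
#' aligned with the image.
#'
#' @param model a [TrainedModel-class].
#' @param image numeric matrix in [0, 1], any size.
#' @return 0/1 integer matrix, 1 = boundary.
#' @export
predictMask <- function(model, image) {
  stopifnot(is(model, "TrainedModel"))
  checkImage(image)
  fp <- model@fieldParams
  field <- orientationDominance(image, derivScale = fp$derivScale,
                                intScale = fp$intScale, eps = fp$eps)
  fm <- buildFeatureMatrix(image, field)
  fmN <- normalizeFeatures(fm, featureStats(model))
  lab <- predictLabels(model, fmN)
  matrix(lab, nrow(image), ncol(image), byrow = TRUE)
}

# Deterministic stratified fold assignment: within each class, a seeded
# shuffle followed by round-robin fold ids.
stratifiedFolds <- function(labels, folds, seed = 1L) {
  withSeed(seed, {
    id <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  })
}

cvAccuracy <- function(x, labels, config, foldId) {
  accs <- vapply(seq_len(max(foldId)), function(k) {
    tr <- foldId != k
    if (length(unique(labels[tr])) < 2L) return(NA_real_)
    fit <- e1071::svm(x = x[tr, , drop = FALSE],
                      y = factor(labels[tr], levels = c(0L, 1L)),
                      kernel = e1071Kernel(config@kernel),
                      cost = config@cost, gamma = config@gamma,
                      scale = FALSE, tolerance = 1e-3)
    pred <- as.integer(as.character(predict(fit, x[!tr, , drop = FALSE])))
    100 * mean(pred == labels[!tr])
  }, numeric(1))
  mean(accs, na.rm = TRUE)
}

#' Exhaustive (C, gamma) grid search with stratified k-fold CV
#'
#' Evaluates every combination of `2^cExponents` and `gammas` by stratified
#' k-fold cross-validated accuracy and returns the best configuration plus
#' the full table. The default grid is a coarsened version of the full search
#' range (C exponents -4..4, gamma 0.02..0.2); the full published search grid
#' (C exponents -4..4 step 0.1, gamma 0.1..2 step 0.001) can be requested via
#' `fullGrid = TRUE`, at cluster-scale cost.
#'
#' @param features a normalised [FeatureMatrix-class].
#' @param labels 0/1 vector.
#' @param cExponents exponents e giving C = 2^e.
#' @param gammas gamma values to scan.
#' @param folds CV folds (>= 2).
#' @param kernel kernel to tune.
#' @param fullGrid replace the grids with the full published search ranges.
#' @param seed seed for the fold assignment.
#' @return list with `best` (an [SvmConfig-class]) and `table` (data.frame
#'   with columns C, gamma, cvAccuracy).
#' @export
gridSearchCV <- function(features, labels, cExponents = -4:4,
                         gammas = seq(0.02, 0.2, by = 0.02), folds = 5L,
                         kernel = "rbf", fullGrid = FALSE, seed = 1L) {
  stopifnot(is(features, "FeatureMatrix"))
  if (fullGrid) {
    cExponents <- seq(-4, 4, by = 0.1)
    gammas <- seq(0.1, 2, by = 0.001)
  }
  if (!length(cExponents) || !length(gammas)) stop("empty search grid")
  labels <- as.integer(labels)
  folds <- as.integer(folds)
  if (folds < 2L) stop("'folds' must be >= 2")
  foldId <- stratifiedFolds(labels, folds, seed)
  grid <- expand.grid(C = 2^cExponents, gamma = gammas,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cvAccuracy <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- svmConfig(kernel = kernel, C = grid$C[i], gamma = grid$gamma[i],
                     cvFolds = folds)
    cvAccuracy(features@values, labels, cfg, foldId)
  }, numeric(1))
  best <- order(-grid$cvAccuracy, grid$C, grid$gamma)[1L]
  list(best = svmConfig(kernel = kernel, C = grid$C[best],
                        gamma = grid$gamma[best], cvFolds = folds),
       table = grid)
}

#' Kernel / gamma sweep with fixed C = 1
#'
#' Trains one model per (kernel, gamma) combination at C = 1 and reports the
#' mean pixel-wise accuracy over the supplied test images, as a
#' gamma-by-kernel table. The linear kernel ignores gamma, so its column is
#' constant by construction.
#'
#' @param features a normalised training [FeatureMatrix-class].
#' @param labels 0/1 training labels.
#' @param testSets list of test cases, each a list with elements `image` and
#'   `mask`.
#' @param kernels kernels to sweep.
#' @param gammas gamma values to sweep.
#' @return data.frame with a `gamma` column and one accuracy column per
#'   kernel; a failed cell propagates as NA.
#' @export
gammaSweep <- function(features, labels,
                       testSets,
                       kernels = c("rbf", "sigmoid", "polynomial", "linear"),
                       gammas = seq(0.02, 0.14, by = 0.01)) {
  stopifnot(is(features, "FeatureMatrix"), length(kernels) > 0,
            length(gammas) > 0, length(testSets) > 0)
  out <- data.frame(gamma = gammas)
  for (kern in kernels) {
    out[[kern]] <- vapply(gammas, function(g) {
      tryCatch({
        model <- trainBoundarySvm(features, labels,
                                  svmConfig(kernel = kern, C = 1, gamma = g))
        accs <- vapply(testSets, function(ts) {
          pred <- predictMask(model, ts$image)
          accuracy(confusionCounts(pred, ts$mask))
        }, numeric(1))
        mean(accs)
      }, error = function(e) NA_real_)
    }, numeric(1))
  }
  out
}
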