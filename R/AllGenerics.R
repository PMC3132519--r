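#' Accuracy of a segmentation
#'
#' The percentage of correctly classified pixels,
#' 100 (TP + TN) / (TP + TN + FP + FN).
#'
#' @param object a [ConfusionCounts-class] object.
#' @return a single percentage in [0, 100].
#' @examples
#' accuracy(confusionCounts(matrix(c(1, 0, 0, 1), 2), matrix(c(1, 0, 0, 0), 2)))
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))

#' Extract the raw numeric matrix from a FeatureMatrix
#' @param object a [FeatureMatrix-class].
#' @return the N x 33 numeric matrix.
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' Per-column normalisation statistics of a FeatureMatrix or TrainedModel
#' @param object a [FeatureMatrix-class] or [TrainedModel-class].
#' @return list with elements `center`, `scale`, `constant` (each length 33).
#' @export
setGeneric("featureStats", function(object) standardGeneric("featureStats"))

#' Number of support vectors in a trained model
#' @param object a [TrainedModel-class].
#' @return integer count.
#' @export
setGeneric("nSupportVectors",
           function(object) standardGeneric("nSupportVectors"))

#' Ranked feature indices of an mRMR ranking
#' @param object a [FeatureRanking-class].
#' @return integer vector, most relevant feature first.
#' @export
setGeneric("rankedFeatures", function(object) standardGeneric("rankedFeatures"))

#' ROC operating points
#' @param object a [RocCurve-class].
#' @return data.frame with columns fpr, tpr, setting.
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))

#' Selected threshold of an automatic thresholding result
#' @param object a [ThresholdResult-class].
#' @return the intensity threshold.
#' @export
setGeneric("thresholdValue",
           function(object) standardGeneric("thresholdValue"))

#' Binary boundary mask carried by a result object
#' @param object a [ThresholdResult-class].
#' @return a 0/1 matrix, 1 = boundary.
#' @export
setGeneric("boundaryMask", function(object) standardGeneric("boundaryMask"))

#' @describeIn accuracy accuracy from confusion counts
#' @export
setMethod("accuracy", "ConfusionCounts", function(object) {
  total <- object@tp + object@tn + object@fp + object@fn
  if (total == 0) stop("no evaluated pixels")
  100 * (object@tp + object@tn) / total
})

#' @rdname featureValues
#' @export
setMethod("featureValues", "FeatureMatrix", function(object) object@values)

#' @rdname featureStats
#' @export
setMethod("featureStats", "FeatureMatrix", function(object)
  list(center = object@center, scale = object@scale,
       constant = object@constant))

#' @rdname featureStats
#' @export
setMethod("featureStats", "TrainedModel", function(object)
  list(center = object@center, scale = object@scale,
       constant = object@constant))

#' @rdname nSupportVectors
#' @export
setMethod("nSupportVectors", "TrainedModel",
          function(object) object@nSupportVectors)

#' @rdname rankedFeatures
#' @export
setMethod("rankedFeatures", "FeatureRanking", function(object) object@order)

#' @rdname rocPoints
#' @export
setMethod("rocPoints", "RocCurve", function(object) object@points)

#' @rdname thresholdValue
#' @export
setMethod("thresholdValue", "ThresholdResult", function(object) object@threshold)

#' @rdname boundaryMask
#' @export
setMethod("boundaryMask", "ThresholdResult", function(object) object@mask)

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf("PhantomConfig: %d x %d px, %d cells, boundary width %d px\n",
              object@width, object@height, object@nCells,
              object@boundaryWidth))
  cat(sprintf("  intensities: boundary %.3f / background %.3f, noise sd %.3f\n",
              object@boundaryMean, object@backgroundMean, object@noiseSigma))
  cat(sprintf("  gaps %.1f%%, speckle density %.2e, seed %d\n",
              100 * object@gapFraction, object@speckleDensity, object@seed))
})

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf("MixtureModel over %d bins: P_O = %.4f, P_b = %.4f\n",
              length(object@condObject), object@priorObject,
              object@priorBackground))
  cat(sprintf("  conditional histogram overlap: %.4f\n",
              sum(pmin(object@condObject, object@condBackground))))
})

setMethod("show", "OrientationField", function(object) {
  m <- sqrt(object@v1^2 + object@v2^2)
  cat(sprintf("OrientationField %d x %d, magnitude range [%.3f, %.3f]\n",
              nrow(object@v1), ncol(object@v1), min(m), max(m)))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d pixels x 33 features (%s)\n",
              nrow(object@values),
              if (object@normalized) "normalised" else "raw"))
})

setMethod("show", "SvmConfig", function(object) {
  cat(sprintf("SvmConfig: kernel %s, C = %g, gamma = %g, %d-fold CV\n",
              object@kernel, object@cost, object@gamma, object@cvFolds))
})

setMethod("show", "TrainedModel", function(object) {
  cat("TrainedModel (1 = boundary)\n")
  show(object@config)
  cat(sprintf("  support vectors: %d\n", object@nSupportVectors))
})

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf("ThresholdResult (%s): threshold %.4f over %d candidates\n",
              object@method, object@threshold, length(object@candidates)))
})

setMethod("show", "FeatureRanking", function(object) {
  cat(sprintf("FeatureRanking of %d features; top 5: %s\n",
              length(object@order),
              paste(utils::head(object@order, 5), collapse = ", ")))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP %g  FP %g  TN %g  FN %g  (accuracy %.2f%%)\n",
              object@tp, object@fp, object@tn, object@fn, accuracy(object)))
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve (%s): %d operating points\n", object@method,
              nrow(object@points)))
})
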