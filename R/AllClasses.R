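#' @import methods
#' @importFrom stats median rnorm runif sd quantile predict
NULL

# Images and masks are deliberately plain matrices: a grayscale image is a
# numeric matrix with intensities in [0, 1], indexed [row, col]; a boundary
# mask is a 0/1 matrix of the same shape with 1 = boundary (foreground).
# Everything derived from them is a validated S4 object below.

#' PhantomConfig: parameters of the synthetic monolayer phantom
#'
#' Describes one synthetic endothelial-monolayer image: a planar mosaic of
#' `nCells` cells whose shared edges form a thin dark boundary network, plus
#' the degradations seen in real silver-stained montages (additive Gaussian
#' noise, boundary gaps, isolated boundary-intensity speckle pixels, a slowly
#' varying quadratic illumination trend and an additive montage-seam step).
#'
#' @slot width,height image size in pixels (>= 16).
#' @slot nCells number of mosaic cells (>= 2).
#' @slot boundaryWidth boundary thickness in pixels.
#' @slot boundaryMean,backgroundMean class intensities in [0, 1].
#' @slot noiseSigma additive Gaussian noise standard deviation.
#' @slot gapFraction fraction of boundary pixels reverted to background, [0, 1).
#' @slot speckleDensity isolated boundary-intensity pixels per unit pixel area.
#' @slot illumCoeffs six coefficients (c0, cx, cy, cxx, cxy, cyy) of the
#'   additive quadratic illumination trend (see [applyIllumination()]).
#' @slot seamColumn column index of the montage seam (NA = no seam).
#' @slot seamOffset additive intensity step right of the seam.
#' @slot seed integer RNG seed; (config, seed) fully determines the output.
#' @seealso [phantomConfig()], [generateMonolayerPhantom()]
#' @exportClass PhantomConfig
setClass("PhantomConfig", representation(
  width = "integer", height = "integer", nCells = "integer",
  boundaryWidth = "integer", boundaryMean = "numeric",
  backgroundMean = "numeric", noiseSigma = "numeric",
  gapFraction = "numeric", speckleDensity = "numeric",
  illumCoeffs = "numeric", seamColumn = "integer", seamOffset = "numeric",
  seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (object@width < 16L || object@height < 16L)
    msg <- c(msg, "width and height must be >= 16")
  if (object@nCells < 2L)
    msg <- c(msg, "nCells must be >= 2 (a mosaic needs at least two cells)")
  if (object@boundaryWidth < 1L)
    msg <- c(msg, "boundaryWidth must be >= 1")
  if (object@boundaryMean < 0 || object@boundaryMean > 1 ||
      object@backgroundMean < 0 || object@backgroundMean > 1)
    msg <- c(msg, "class mean intensities must lie in [0, 1]")
  if (object@gapFraction < 0 || object@gapFraction >= 1)
    msg <- c(msg, "gapFraction must lie in [0, 1)")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@speckleDensity < 0) msg <- c(msg, "speckleDensity must be >= 0")
  if (length(object@illumCoeffs) != 6L || any(!is.finite(object@illumCoeffs)))
    msg <- c(msg, "illumCoeffs must be 6 finite numbers")
  if (object@boundaryMean == object@backgroundMean && object@noiseSigma == 0)
    msg <- c(msg, "degenerate config: identical class means with zero noise")
  if (length(msg)) msg else TRUE
})

#' MixtureModel: supervised two-class intensity mixture
#'
#' The per-pixel intensity model P(i) = P_O P(i|O) + P_b P(i|b): class priors
#' are pixel fractions and the conditionals are normalised per-class intensity
#' histograms over an equal-width bin grid on [0, 1]. Fitted from labelled
#' pixels by [fitIntensityMixture()]; its overlap quantifies why a single
#' global intensity threshold cannot separate boundary from background.
#'
#' @slot priorObject,priorBackground class priors, summing to 1.
#' @slot condObject,condBackground per-bin conditional probabilities (sum 1).
#' @slot breaks bin edges on [0, 1] (length nBins + 1).
#' @exportClass MixtureModel
setClass("MixtureModel", representation(
  priorObject = "numeric", priorBackground = "numeric",
  condObject = "numeric", condBackground = "numeric", breaks = "numeric"))

setValidity("MixtureModel", function(object) {
  msg <- character()
  if (abs(object@priorObject + object@priorBackground - 1) > 1e-12)
    msg <- c(msg, "priors must sum to 1")
  if (object@priorObject < 0 || object@priorBackground < 0)
    msg <- c(msg, "priors must be non-negative")
  for (nm in c("condObject", "condBackground")) {
    p <- slot(object, nm)
    if (any(p < 0)) msg <- c(msg, paste(nm, "has negative entries"))
    if (abs(sum(p) - 1) > 1e-9) msg <- c(msg, paste(nm, "must sum to 1"))
    if (length(p) != length(object@breaks) - 1L)
      msg <- c(msg, paste(nm, "length does not match the bin grid"))
  }
  if (length(msg)) msg else TRUE
})

#' OrientationField: per-pixel orientation-dominance vector field
#'
#' A two-component vector per pixel. The vector's direction is the locally
#' dominant structure orientation in double-angle form (so an orientation and
#' its 180-degree rotation coincide) and its magnitude in [0, 1] measures
#' anisotropy: near 0 on isotropic neighbourhoods, near 1 on strongly oriented
#' ones. Built exclusively from band-pass Gaussian-derivative filters, so it
#' is quasi-invariant to slow additive illumination changes.
#'
#' @slot v1,v2 component matrices, aligned with the source image.
#' @seealso [orientationDominance()]
#' @exportClass OrientationField
setClass("OrientationField", representation(v1 = "matrix", v2 = "matrix"))

setValidity("OrientationField", function(object) {
  if (!identical(dim(object@v1), dim(object@v2)))
    return("v1 and v2 must have identical dimensions")
  mag2 <- object@v1^2 + object@v2^2
  if (any(mag2 > 1 + 1e-9)) return("vector magnitudes must lie in [0, 1]")
  TRUE
})

#' FeatureMatrix: per-pixel 33-dimensional feature vectors
#'
#' One row per pixel in row-major scan order (or per requested pixel), with a
#' fixed 33-column layout: columns 1-9 the 3x3 intensity patch (row-major,
#' centre pixel = column 5); columns 10-27 the 3x3 patch of the orientation
#' dominance field (per patch position: v1 then v2); columns 28-33 the patch
#' statistics Med, Range, E, M2, M3, M4. Carries its per-column normalisation
#' state (population mean/sd) so train-time statistics can be replayed
#' verbatim at test time.
#'
#' @slot values numeric matrix with exactly 33 columns.
#' @slot center,scale per-column normalisation statistics (length 33, NA
#'   until normalisation has been computed or supplied).
#' @slot constant logical flag per column: TRUE where the training column had
#'   zero variance (such columns are centred only).
#' @slot normalized whether `values` is in normalised units.
#' @seealso [buildFeatureMatrix()], [normalizeFeatures()]
#' @exportClass FeatureMatrix
setClass("FeatureMatrix", representation(
  values = "matrix", center = "numeric", scale = "numeric",
  constant = "logical", normalized = "logical"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) != 33L)
    msg <- c(msg, "feature matrix must have exactly 33 columns")
  if (length(object@center) != 33L || length(object@scale) != 33L ||
      length(object@constant) != 33L)
    msg <- c(msg, "normalisation statistics must have 33 entries")
  if (object@normalized && anyNA(object@center))
    msg <- c(msg, "a normalised matrix must carry its statistics")
  if (length(msg)) msg else TRUE
})

#' SvmConfig: support-vector-machine hyper-parameters
#'
#' @slot kernel one of "rbf", "sigmoid", "polynomial", "linear".
#' @slot cost the C cost parameter (> 0); default operating point C = 1
#'   (slot named `cost` to avoid clashing with `new()`'s Class argument).
#' @slot gamma kernel width for kernels that use it (> 0); default 0.14.
#' @slot cvFolds folds for cross-validated model selection (>= 2).
#' @exportClass SvmConfig
setClass("SvmConfig", representation(
  kernel = "character", cost = "numeric", gamma = "numeric", cvFolds = "integer"))

setValidity("SvmConfig", function(object) {
  msg <- character()
  if (!object@kernel %in% c("rbf", "sigmoid", "polynomial", "linear"))
    msg <- c(msg, "kernel must be one of rbf, sigmoid, polynomial, linear")
  if (object@cost <= 0) msg <- c(msg, "C must be > 0")
  if (object@kernel != "linear" && object@gamma <= 0)
    msg <- c(msg, "gamma must be > 0 for kernels that use it")
  if (object@cvFolds < 2L) msg <- c(msg, "cvFolds must be >= 2")
  if (length(msg)) msg else TRUE
})

#' TrainedModel: a fitted per-pixel boundary classifier
#'
#' Wraps the fitted SVM decision function together with everything needed to
#' apply it to a new image: the hyper-parameters, the training-set
#' normalisation statistics and the orientation-field parameters. Label
#' convention: 1 = boundary.
#'
#' @slot fit the underlying [e1071::svm] fit.
#' @slot config the [SvmConfig-class] used.
#' @slot center,scale,constant normalisation statistics from training.
#' @slot fieldParams orientation-field parameters (derivScale, intScale, eps).
#' @slot nSupportVectors number of support vectors in the fit.
#' @exportClass TrainedModel
setClass("TrainedModel", representation(
  fit = "ANY", config = "SvmConfig", center = "numeric", scale = "numeric",
  constant = "logical", fieldParams = "list", nSupportVectors = "integer"))

#' ThresholdResult: an automatic global threshold and its criterion curve
#'
#' @slot threshold the selected intensity threshold.
#' @slot mask the resulting boundary mask (dark side = boundary by default).
#' @slot criterion per-candidate criterion values (between-class variance for
#'   Otsu, minimum-error J(t) for Kittler; NA at skipped candidates).
#' @slot candidates the candidate thresholds scanned.
#' @slot method "otsu" or "kittler".
#' @exportClass ThresholdResult
setClass("ThresholdResult", representation(
  threshold = "numeric", mask = "matrix", criterion = "numeric",
  candidates = "numeric", method = "character"))

setValidity("ThresholdResult", function(object) {
  msg <- character()
  if (length(object@criterion) != length(object@candidates))
    msg <- c(msg, "criterion and candidates lengths differ")
  if (!all(object@mask %in% c(0, 1)))
    msg <- c(msg, "mask must be binary")
  if (length(msg)) msg else TRUE
})

#' FeatureRanking: mRMR ordering of the 33 features
#'
#' @slot order permutation of 1..33, most relevant first.
#' @slot relevance mutual information with the class label, per step (bits).
#' @slot redundancy mean mutual information with already-selected features,
#'   per step (bits; 0 for the first pick).
#' @slot group feature group per selected index: intensity, orientation or
#'   statistic.
#' @exportClass FeatureRanking
setClass("FeatureRanking", representation(
  order = "integer", relevance = "numeric", redundancy = "numeric",
  group = "character"))

setValidity("FeatureRanking", function(object) {
  n <- length(object@order)
  msg <- character()
  if (anyDuplicated(object@order)) msg <- c(msg, "ranking contains duplicates")
  if (any(object@order < 1L) || any(object@order > 33L))
    msg <- c(msg, "feature indices must lie in 1..33")
  if (length(object@relevance) != n || length(object@redundancy) != n ||
      length(object@group) != n)
    msg <- c(msg, "score vectors must match the ranking length")
  if (any(!is.finite(object@relevance)) || any(!is.finite(object@redundancy)))
    msg <- c(msg, "scores must be finite")
  if (length(msg)) msg else TRUE
})

#' ConfusionCounts: pixel-wise confusion counts
#'
#' Positive class = boundary. [accuracy()] computes
#' 100 (TP + TN) / (TP + TN + FP + FN).
#'
#' @slot tp,fp,tn,fn pixel counts.
#' @exportClass ConfusionCounts
setClass("ConfusionCounts", representation(
  tp = "numeric", fp = "numeric", tn = "numeric", fn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(v < 0)) return("counts must be non-negative")
  TRUE
})

#' RocCurve: operating points of a segmenter family
#'
#' One (false-positive rate, true-positive rate) point per swept setting,
#' deduplicated and sorted by FPR.
#'
#' @slot points data.frame with columns fpr, tpr, setting.
#' @slot method label of the method that produced the sweep.
#' @exportClass RocCurve
setClass("RocCurve", representation(points = "data.frame", method = "character"))

setValidity("RocCurve", function(object) {
  p <- object@points
  if (!all(c("fpr", "tpr", "setting") %in% names(p)))
    return("points must have columns fpr, tpr, setting")
  if (nrow(p) && (any(p$fpr < -1e-12) || any(p$fpr > 1 + 1e-12) ||
                  any(p$tpr < -1e-12) || any(p$tpr > 1 + 1e-12)))
    return("rates must lie in [0, 1]")
  TRUE
})
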