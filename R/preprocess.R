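# Illumination correction (quadratic background fit / subtraction), montage
# seam compensation, and the supervised two-class intensity mixture model that
# quantifies why global thresholding fails on these images.

#' Least-squares quadratic background fit
#'
#' Fits the additive second-order illumination surface
#' c0 + cx x + cy y + cxx x^2 + cxy x y + cyy y^2 (the same basis and
#' [-1, 1] coordinate normalisation as [applyIllumination()]) to the image by
#' ordinary least squares over all pixels.
#'
#' @param image numeric matrix with at least 6 pixels.
#' @return named numeric vector of 6 coefficients (c0, cx, cy, cxx, cxy, cyy).
#' @examples
#' img <- applyIllumination(matrix(0.5, 32, 32), c(0, 0.1, 0, 0.05, 0, 0))
#' round(fitQuadraticBackground(img), 3)
#' @export
fitQuadraticBackground <- function(image) {
  checkImage(image)
  h <- nrow(image); w <- ncol(image)
  if (h * w < 6L) stop("need at least 6 pixels to fit 6 coefficients")
  x <- if (w > 1) 2 * (seq_len(w) - 1) / (w - 1) - 1 else 0
  y <- if (h > 1) 2 * (seq_len(h) - 1) / (h - 1) - 1 else 0
  X <- rep(x, each = h)
  Y <- rep(y, times = w)
  D <- cbind(1, X, Y, X^2, X * Y, Y^2)
  fit <- tryCatch(qr.solve(qr(D), as.vector(image)),
                  error = function(e) stop(
                    "rank-deficient quadratic design (degenerate image shape)"))
  if (qr(D)$rank < 6L)
    stop("rank-deficient quadratic design (degenerate image shape)")
  stats::setNames(as.numeric(fit), c("c0", "cx", "cy", "cxx", "cxy", "cyy"))
}

#' Subtract a fitted background surface, preserving mean brightness
#'
#' Removes the quadratic surface described by `coeffs` and adds back its
#' global mean so the corrected image keeps the original overall brightness,
#' then clips to [0, 1].
#'
#' @param image numeric matrix in [0, 1].
#' @param coeffs six surface coefficients, typically from
#'   [fitQuadraticBackground()].
#' @return the corrected image.
#' @export
subtractBackground <- function(image, coeffs) {
  checkImage(image)
  if (length(coeffs) != 6L || any(!is.finite(coeffs)))
    stop("'coeffs' must be 6 finite numbers")
  s <- quadraticSurface(nrow(image), ncol(image), coeffs)
  clip01(image - s + mean(s))
}

#' Compensate a montage-seam intensity step
#'
#' Estimates the additive offset across a montage seam from the mean
#' intensities of two flanking strips (`strip_width` columns each) and shifts
#' every pixel right of the seam by (left strip mean - right strip mean).
#'
#' @param image numeric matrix in [0, 1].
#' @param column first column of the right-hand acquisition.
#' @param stripWidth strip width in pixels on each side of the seam.
#' @return the compensated image, clipped to [0, 1].
#' @export
compensateSeam <- function(image, column, stripWidth = 10L) {
  checkImage(image)
  w <- ncol(image)
  if (column <= 1L || column > w) stop("'column' out of range")
  if (column - stripWidth < 1L || column + stripWidth - 1L > w)
    stop("'stripWidth' strips do not fit around the seam")
  left <- mean(image[, (column - stripWidth):(column - 1L)])
  right <- mean(image[, column:(column + stripWidth - 1L)])
  image[, column:w] <- image[, column:w] + (left - right)
  clip01(image)
}

#' Fit the supervised two-class intensity mixture
#'
#' Estimates P(i) = P_O P(i|O) + P_b P(i|b) from labelled pixels: the priors
#' are the class pixel fractions and the conditionals are normalised per-class
#' intensity histograms over `nBins` equal-width bins on [0, 1]. The overlap
#' of the two conditionals (see [histogramOverlap()]) measures how far the
#' classes are from separable by any single global threshold.
#'
#' @param image numeric matrix in [0, 1].
#' @param mask aligned 0/1 boundary mask; both classes must be present.
#' @param nBins number of equal-width histogram bins on [0, 1].
#' @return a [MixtureModel-class].
#' @export
fitIntensityMixture <- function(image, mask, nBins = 64L) {
  checkImage(image)
  checkMask(mask, image)
  if (!any(mask == 1L) || !any(mask == 0L))
    stop("both classes must be present in the mask")
  nBins <- as.integer(nBins)
  binOf <- function(v) pmin(floor(v * nBins), nBins - 1L) + 1L
  counts <- function(v) tabulate(binOf(v), nbins = nBins)
  obj <- counts(image[mask == 1L])
  bg <- counts(image[mask == 0L])
  nObj <- sum(mask == 1L)
  new("MixtureModel",
      priorObject = nObj / length(mask),
      priorBackground = 1 - nObj / length(mask),
      condObject = obj / sum(obj),
      condBackground = bg / sum(bg),
      breaks = seq(0, 1, length.out = nBins + 1L))
}

#' Pooled intensity density P(i) of a mixture model
#'
#' @param model a [MixtureModel-class].
#' @return data.frame with columns `mid` (bin midpoints), `pObject`,
#'   `pBackground` (conditionals) and `pTotal` (the prior-weighted mixture;
#'   sums to 1 over bins).
#' @export
mixtureDensity <- function(model) {
  stopifnot(is(model, "MixtureModel"))
  mids <- (utils::head(model@breaks, -1) + utils::tail(model@breaks, -1)) / 2
  data.frame(mid = mids,
             pObject = model@condObject,
             pBackground = model@condBackground,
             pTotal = model@priorObject * model@condObject +
               model@priorBackground * model@condBackground)
}

#' Overlap coefficient of the class-conditional intensity histograms
#'
#' Sum over bins of min(P(i|O), P(i|b)); 0 for perfectly separable classes,
#' 1 for identical distributions. Large values are why a single global
#' intensity threshold cannot segment these images.
#'
#' @param model a [MixtureModel-class].
#' @return overlap coefficient in [0, 1].
#' @export
histogramOverlap <- function(model) {
  stopifnot(is(model, "MixtureModel"))
  sum(pmin(model@condObject, model@condBackground))
}

#' Best achievable global-threshold accuracy against a ground-truth mask
#'
#' Exhaustively scans `nLevels` candidate thresholds on [0, 1] and reports the
#' best pixel-wise accuracy a single global intensity threshold can reach on
#' this image (boundary = dark side). An upper bound for any automatic
#' thresholding method, used to contrast thresholding with the SVM pipeline.
#'
#' @param image numeric matrix in [0, 1].
#' @param mask aligned 0/1 ground-truth mask.
#' @param nLevels number of evenly spaced candidate thresholds.
#' @return list with `threshold` (the argmax) and `accuracy` (percent).
#' @export
bestGlobalThresholdAccuracy <- function(image, mask, nLevels = 256L) {
  checkImage(image)
  checkMask(mask, image)
  cand <- seq(0, 1, length.out = nLevels)
  accs <- vapply(cand, function(t)
    accuracy(confusionCounts(thresholdMask(image, t), mask)), numeric(1))
  best <- which.max(accs)
  list(threshold = cand[best], accuracy = accs[best])
}
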