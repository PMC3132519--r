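# The 33-dimensional per-pixel feature space: a 3x3 intensity patch, the 3x3
# patch of an orientation-dominance vector field, and six patch statistics
# (Med, Range, E, M2, M3, M4), plus train/test-consistent normalisation.

#' Fixed names of the 33 feature columns
#'
#' Columns 1-9: the 3x3 intensity patch in row-major order (centre = I5).
#' Columns 10-27: the orientation-dominance vectors at the 9 patch positions,
#' v1 before v2. Columns 28-33: Med, Range, E, M2, M3, M4.
#'
#' @return character vector of length 33.
#' @export
featureNames33 <- function() {
  c(paste0("I", 1:9),
    paste0("O", rep(1:9, each = 2), c("v1", "v2")),
    "Med", "Range", "E", "M2", "M3", "M4")
}

#' Feature group of each of the 33 columns
#'
#' @return character vector of length 33 with values "intensity" (9),
#'   "orientation" (18) and "statistic" (6).
#' @export
featureGroups <- function() {
  c(rep("intensity", 9), rep("orientation", 18), rep("statistic", 6))
}

#' Orientation-dominance field of an image
#'
#' Computes a per-pixel two-component vector whose direction is the locally
#' dominant structure orientation in double-angle form and whose magnitude in
#' [0, 1] measures anisotropy. The field is built from Gaussian
#' second-derivative (band-pass) filters at `derivScale`: with the local
#' Hessian responses (Ixx, Ixy, Iyy), the double-angle direction is that of
#' -(Ixx - Iyy, 2 Ixy) — so for a dark line, atan2(v2, v1) / 2 is the line
#' orientation — and the magnitude is the normalised eigenvalue contrast
#' |l1 - l2| / (|l1| + |l2| + eps), which is 0 on isotropic neighbourhoods and
#' approaches 1 on strongly oriented ones. The vector components are then
#' smoothed at `intScale`, which cannot push the magnitude above 1. Because
#' every filter is DC-free and symmetric, constant and linear-ramp intensity
#' offsets produce exactly zero response, making the field quasi-invariant to
#' slow illumination changes.
#'
#' Internally the field is the classical orientation tensor: the local second
#' moment of Gaussian-derivative responses, smoothed at the integration
#' scale, whose eigen-structure gives the dominant axis and a coherence-type
#' anisotropy measure. The tensor is quadratic in the filter responses, so
#' the double-angle vector does not flip sign between the centre and the
#' flanks of a thin line.
#'
#' @param image numeric matrix in [0, 1].
#' @param derivScale Gaussian scale of the derivative filters, pixels (> 0).
#' @param intScale integration (smoothing) scale of the vector field, pixels;
#'   0 disables smoothing.
#' @param eps regulariser for flat regions.
#' @return an [OrientationField-class].
#' @examples
#' img <- matrix(0.6, 32, 32); img[16, ] <- 0.2   # dark horizontal line
#' f <- orientationDominance(img)
#' sqrt(f@v1[16, 16]^2 + f@v2[16, 16]^2)          # strong anisotropy
#' @export
orientationDominance <- function(image, derivScale = 1.0, intScale = 2.0,
                                 eps = 1e-6) {
  checkImage(image)
  if (derivScale <= 0) stop("'derivScale' must be > 0")
  if (intScale < 0) stop("'intScale' must be >= 0")
  g <- gaussKernel(derivScale)
  g1 <- gaussDeriv1Kernel(derivScale)
  gx <- convSep(image, g, g1)    # d/dx, x = column
  gy <- convSep(image, g1, g)    # d/dy, y = row
  jxx <- gx^2
  jyy <- gy^2
  jxy <- gx * gy
  if (intScale > 0) {
    gi <- gaussKernel(intScale)
    jxx <- convSep(jxx, gi, gi)
    jyy <- convSep(jyy, gi, gi)
    jxy <- convSep(jxy, gi, gi)
  }
  dd <- jxx - jyy
  od <- 2 * jxy
  amp <- sqrt(dd^2 + od^2)       # l1 - l2 (eigenvalues are >= 0)
  trace <- jxx + jyy             # l1 + l2
  mag <- amp / (trace + eps)
  safe <- pmax(amp, .Machine$double.xmin)
  # minus: the dominant-gradient axis is across the structure; the double
  # angle of the structure itself is that axis rotated by 90 degrees
  v1 <- -mag * dd / safe
  v2 <- -mag * od / safe
  new("OrientationField", v1 = v1, v2 = v2)
}

# N x 9 matrix of 3x3 neighbourhoods (row-major patch order, reflect padding)
# for every pixel of `m` in row-major scan order.
patchMatrix <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- reflectPad(m, 1L)
  out <- matrix(0, h * w, 9L)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    out[, k] <- rowMajor(p[(2L + dr):(h + 1L + dr),
                           (2L + dc):(w + 1L + dc), drop = FALSE])
  }
  out
}

#' 3x3 neighbourhood intensities of one pixel
#'
#' Returns the nine intensities of the 3x3 neighbourhood of (`row`, `col`) in
#' row-major order with the centre at position 5. Borders are handled by
#' symmetric reflection, so no artificial dark rim is fabricated.
#'
#' @param image numeric matrix in [0, 1].
#' @param row,col 1-based pixel coordinates.
#' @return numeric vector of length 9.
#' @export
patchIntensities <- function(image, row, col) {
  checkImage(image)
  h <- nrow(image); w <- ncol(image)
  if (row < 1L || row > h || col < 1L || col > w)
    stop("pixel index out of bounds")
  refl <- function(i, n) ifelse(i < 1L, 1L - i, ifelse(i > n, 2L * n + 1L - i, i))
  v <- numeric(9)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    v[k] <- image[refl(row + dr, h), refl(col + dc, w)]
  }
  v
}

#' Six statistical features of a 3x3 intensity patch
#'
#' Med = median of the nine values; Range = max - min; E = sum of squared
#' intensities; M2, M3, M4 = central moments (1/n) sum (I - mu)^r for
#' r = 2, 3, 4 with n = 9 and mu the patch mean.
#'
#' @param patch numeric vector of 9 finite values.
#' @return named numeric vector (Med, Range, E, M2, M3, M4).
#' @examples
#' patchStatistics(0:8)
#' @export
patchStatistics <- function(patch) {
  if (length(patch) != 9L || any(!is.finite(patch)))
    stop("'patch' must be 9 finite values")
  mu <- mean(patch)
  d <- patch - mu
  c(Med = median(patch), Range = max(patch) - min(patch),
    E = sum(patch^2), M2 = mean(d^2), M3 = mean(d^3), M4 = mean(d^4))
}

# Vectorised patch statistics for an N x 9 patch matrix.
patchStatisticsMatrix <- function(P) {
  mu <- rowMeans(P)
  D <- P - mu
  cbind(Med = apply(P, 1L, median),
        Range = do.call(pmax, as.data.frame(P)) -
          do.call(pmin, as.data.frame(P)),
        E = rowSums(P^2), M2 = rowMeans(D^2),
        M3 = rowMeans(D^3), M4 = rowMeans(D^4))
}

#' Build the 33-column per-pixel feature matrix
#'
#' Maps each requested pixel (default: every pixel, row-major scan order) to
#' its 33-dimensional feature vector: the 3x3 intensity patch (columns 1-9),
#' the 3x3 patch of the orientation-dominance field with v1 before v2 per
#' position (columns 10-27), and the six patch statistics recomputed from the
#' intensity patch (columns 28-33). The result is unnormalised; see
#' [normalizeFeatures()].
#'
#' @param image numeric matrix in [0, 1].
#' @param field an [OrientationField-class] aligned with the image; computed
#'   with default parameters when omitted.
#' @param pixels optional integer matrix with columns (row, col) selecting
#'   pixels; NULL takes all pixels in row-major order.
#' @return a [FeatureMatrix-class] with one row per pixel.
#' @examples
#' ph <- generateMonolayerPhantom(phantomConfig(width = 32, height = 32,
#'                                              nCells = 4, seed = 1))
#' fm <- buildFeatureMatrix(ph$image)
#' dim(featureValues(fm))
#' @export
buildFeatureMatrix <- function(image, field = NULL, pixels = NULL) {
  checkImage(image)
  if (is.null(field)) field <- orientationDominance(image)
  stopifnot(is(field, "OrientationField"))
  if (!identical(dim(field@v1), dim(image)))
    stop("orientation field is not aligned with the image")
  h <- nrow(image); w <- ncol(image)

  PI <- patchMatrix(image)
  P1 <- patchMatrix(field@v1)
  P2 <- patchMatrix(field@v2)

  if (!is.null(pixels)) {
    pixels <- as.matrix(pixels)
    if (ncol(pixels) != 2L) stop("'pixels' must have columns (row, col)")
    if (any(pixels[, 1] < 1L) || any(pixels[, 1] > h) ||
        any(pixels[, 2] < 1L) || any(pixels[, 2] > w))
      stop("pixel index out of bounds")
    idx <- (pixels[, 1] - 1L) * w + pixels[, 2]
    PI <- PI[idx, , drop = FALSE]
    P1 <- P1[idx, , drop = FALSE]
    P2 <- P2[idx, , drop = FALSE]
  }

  orient <- matrix(0, nrow(PI), 18L)
  orient[, seq(1L, 17L, by = 2L)] <- P1
  orient[, seq(2L, 18L, by = 2L)] <- P2

  vals <- cbind(PI, orient, patchStatisticsMatrix(PI))
  colnames(vals) <- featureNames33()
  new("FeatureMatrix", values = vals,
      center = rep(NA_real_, 33L), scale = rep(NA_real_, 33L),
      constant = rep(NA, 33L), normalized = FALSE)
}

#' Normalise feature columns to zero mean and unit standard deviation
#'
#' In training mode (`stats = NULL`) the per-column mean and population
#' (1/N) standard deviation are computed from this matrix, applied, and
#' stored so they can be replayed on test data. In test mode the supplied
#' statistics are applied unchanged. Columns with zero variance in training
#' are centred only (flagged in `constant`), with a warning.
#'
#' @param matrix a raw [FeatureMatrix-class].
#' @param stats optional statistics list (`center`, `scale`, `constant`) from
#'   [featureStats()] of a training matrix or model.
#' @return a normalised [FeatureMatrix-class] carrying the statistics used.
#' @export
normalizeFeatures <- function(matrix, stats = NULL) {
  stopifnot(is(matrix, "FeatureMatrix"))
  if (matrix@normalized)
    stop("feature matrix is already normalised")
  x <- matrix@values
  if (is.null(stats)) {
    if (nrow(x) < 2L) stop("need >= 2 rows to estimate normalisation stats")
    center <- colMeans(x)
    scale <- sqrt(colMeans(sweep(x, 2L, center)^2))
    constant <- scale == 0
    if (any(constant)) {
      warning(sum(constant), " zero-variance feature column(s) centred only: ",
              paste(featureNames33()[constant], collapse = ", "))
      scale[constant] <- 1
    }
  } else {
    if (!all(c("center", "scale", "constant") %in% names(stats)))
      stop("'stats' must carry center, scale and constant")
    center <- stats$center; scale <- stats$scale; constant <- stats$constant
    if (length(center) != 33L || length(scale) != 33L)
      stop("normalisation statistics must have 33 entries")
  }
  z <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  colnames(z) <- featureNames33()
  new("FeatureMatrix", values = z, center = as.numeric(center),
      scale = as.numeric(scale), constant = as.logical(constant),
      normalized = TRUE)
}
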