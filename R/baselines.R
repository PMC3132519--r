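# Classical baseline segmenters: Otsu and Kittler-Illingworth minimum-error
# global thresholding (each with its full criterion curve, so tests can check
# the selected threshold against an exhaustive scan) and Canny edge detection,
# plus the threshold sweeps that feed ROC construction.

histCounts <- function(image, nLevels) {
  v <- as.vector(image)
  bin <- pmin(floor(v * nLevels), nLevels - 1L) + 1L
  tabulate(bin, nbins = nLevels)
}

#' Otsu automatic threshold
#'
#' Selects the intensity threshold maximising the between-class variance
#' w0 w1 (mu0 - mu1)^2 over an `nLevels`-bin histogram on [0, 1]. Candidates
#' are the interior bin edges; an exactly tied plateau of the criterion (runs
#' of empty bins) resolves to its middle candidate. By default the dark side
#' is labelled boundary.
#'
#' @param image numeric, non-constant matrix in [0, 1].
#' @param nLevels histogram resolution (default 256, the 8-bit convention).
#' @param darkBoundary label the dark side as boundary (default TRUE).
#' @return a [ThresholdResult-class] with the full criterion curve.
#' @export
otsuThreshold <- function(image, nLevels = 256L, darkBoundary = TRUE) {
  checkImage(image)
  if (diff(range(image)) == 0) stop("cannot threshold a constant image")
  nLevels <- as.integer(nLevels)
  h <- histCounts(image, nLevels)
  n <- sum(h)
  mids <- (seq_len(nLevels) - 0.5) / nLevels
  cw <- cumsum(h)                    # pixels at or below each bin
  cm <- cumsum(h * mids)
  total <- cm[nLevels]
  k <- seq_len(nLevels - 1L)
  w0 <- cw[k] / n
  w1 <- 1 - w0
  crit <- rep(NA_real_, nLevels - 1L)
  ok <- w0 > 0 & w1 > 0
  mu0 <- cm[k][ok] / cw[k][ok]
  mu1 <- (total - cm[k][ok]) / (n - cw[k][ok])
  crit[ok] <- w0[ok] * w1[ok] * (mu0 - mu1)^2
  best <- criterionOptimum(crit, maximize = TRUE)
  thr <- best / nLevels
  new("ThresholdResult", threshold = thr,
      mask = thresholdMask(image, thr, darkBoundary),
      criterion = crit, candidates = k / nLevels, method = "otsu")
}

#' Kittler-Illingworth minimum-error threshold
#'
#' Selects the threshold minimising the minimum-error criterion
#' J(t) = 1 + 2 (w0 log s0 + w1 log s1) - 2 (w0 log w0 + w1 log w1),
#' where w, s are the weight and standard deviation of the two tentative
#' classes split at t, computed from an `nLevels`-bin histogram. Candidates
#' with an empty or zero-variance class are skipped.
#'
#' @inheritParams otsuThreshold
#' @return a [ThresholdResult-class] with the J(t) curve (NA at skipped
#'   candidates).
#' @export
kittlerThreshold <- function(image, nLevels = 256L, darkBoundary = TRUE) {
  checkImage(image)
  if (diff(range(image)) == 0) stop("cannot threshold a constant image")
  nLevels <- as.integer(nLevels)
  h <- histCounts(image, nLevels)
  n <- sum(h)
  mids <- (seq_len(nLevels) - 0.5) / nLevels
  cw <- cumsum(h)
  cm <- cumsum(h * mids)
  cs <- cumsum(h * mids^2)
  k <- seq_len(nLevels - 1L)
  w0 <- cw[k] / n
  w1 <- 1 - w0
  crit <- rep(NA_real_, nLevels - 1L)
  ok <- cw[k] > 0 & cw[k] < n
  mu0 <- cm[k] / cw[k]
  mu1 <- (cm[nLevels] - cm[k]) / (n - cw[k])
  var0 <- cs[k] / cw[k] - mu0^2
  var1 <- (cs[nLevels] - cs[k]) / (n - cw[k]) - mu1^2
  ok <- ok & var0 > 1e-12 & var1 > 1e-12
  crit[ok] <- 1 + 2 * (w0[ok] * log(sqrt(var0[ok])) +
                       w1[ok] * log(sqrt(var1[ok]))) -
              2 * (w0[ok] * log(w0[ok]) + w1[ok] * log(w1[ok]))
  if (!any(ok)) stop("no valid Kittler candidate threshold")
  best <- criterionOptimum(crit, maximize = FALSE)
  thr <- best / nLevels
  new("ThresholdResult", threshold = thr,
      mask = thresholdMask(image, thr, darkBoundary),
      criterion = crit, candidates = k / nLevels, method = "kittler")
}

# Gradient magnitude after non-maximum suppression: the reusable part of
# Canny, computed once per (image, sigma) so threshold sweeps are cheap.
cannyNonmax <- function(image, sigma) {
  g <- gaussKernel(sigma)
  g1 <- gaussDeriv1Kernel(sigma)
  gx <- convSep(image, g, g1)
  gy <- convSep(image, g1, g)
  mag <- sqrt(gx^2 + gy^2)
  mag[mag < 1e-12] <- 0              # floor float residue of flat regions
  h <- nrow(mag); w <- ncol(mag)
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- mag
  nb <- function(dr, dc) p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- (floor(ang / (pi / 4) + 0.5)) %% 4      # 0:E, 1:SE, 2:S, 3:SW
  # >= along the positive direction, > along the negative one: a symmetric
  # two-pixel ridge plateau keeps exactly one pixel
  keep <- sector == 0 & mag >= nb(0L, 1L) & mag > nb(0L, -1L)
  keep <- keep | (sector == 1 & mag >= nb(1L, 1L) & mag > nb(-1L, -1L))
  keep <- keep | (sector == 2 & mag >= nb(1L, 0L) & mag > nb(-1L, 0L))
  keep <- keep | (sector == 3 & mag >= nb(1L, -1L) & mag > nb(-1L, 1L))
  out <- mag
  out[!keep] <- 0
  out
}

# Double-threshold hysteresis on a non-maximum-suppressed magnitude map:
# weak edge pixels survive only in connected components containing a strong
# pixel.
cannyHysteresis <- function(nms, lowAbs, highAbs) {
  weak <- nms >= lowAbs & nms > 0
  strong <- nms >= highAbs & nms > 0
  if (!any(strong))
    return(matrix(0L, nrow(nms), ncol(nms)))
  lbl <- EBImage::bwlabel(weak)
  keepIds <- unique(lbl[strong])
  keepIds <- keepIds[keepIds > 0]
  matrix(as.integer(lbl %in% keepIds & weak), nrow(nms), ncol(nms))
}

#' Canny edge detection
#'
#' Standard Canny: Gaussian-derivative gradients, non-maximum suppression
#' along the quantised gradient direction, and double-threshold hysteresis.
#' `low` and `high` are fractions of the maximum suppressed gradient
#' magnitude. Note that on a thin dark line Canny marks the two flanking
#' intensity edges, not the line centre - the structural reason edge
#' detection is penalised against centreline ground truth in this regime.
#'
#' @param image numeric matrix in [0, 1].
#' @param sigma Gaussian derivative scale in pixels.
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   magnitude, 0 <= low <= high <= 1.
#' @return 0/1 integer matrix of edge pixels.
#' @export
cannyEdges <- function(image, sigma = 1.0, low = 0.1, high = 0.2) {
  checkImage(image)
  if (!(low >= 0 && low <= high && high <= 1))
    stop("need 0 <= low <= high <= 1")
  nms <- cannyNonmax(image, sigma)
  m <- max(nms)
  if (m == 0) return(matrix(0L, nrow(image), ncol(image)))
  cannyHysteresis(nms, low * m, high * m)
}

#' Threshold sweep for ROC construction
#'
#' Produces one boundary mask per candidate threshold, with `n` candidates
#' evenly spaced strictly inside the image's intensity range (63 by default,
#' the detection-threshold count used for the minimum-error ROC sweep).
#'
#' @param image numeric matrix in [0, 1].
#' @param n number of candidate thresholds.
#' @param darkBoundary label the dark side boundary (default TRUE).
#' @return list of entries, each a list with `mask` and `setting`.
#' @export
thresholdSweep <- function(image, n = 63L, darkBoundary = TRUE) {
  checkImage(image)
  rng <- range(image)
  if (diff(rng) == 0) stop("cannot sweep a constant image")
  cand <- rng[1] + seq_len(n) * diff(rng) / (n + 1L)
  lapply(cand, function(t)
    list(mask = thresholdMask(image, t, darkBoundary),
         setting = sprintf("t=%.6f", t)))
}

#' Canny (low, high) hysteresis sweep for ROC construction
#'
#' Sweeps an `n` x `n` grid of hysteresis settings (961 settings for the
#' default n = 31): `n` high thresholds spaced over the magnitude range and,
#' for each, `n` low-to-high ratios - so every setting is a valid
#' low <= high pair. Gradient computation and non-maximum suppression are
#' shared across the grid.
#'
#' @param image numeric matrix in [0, 1].
#' @param sigma Gaussian derivative scale in pixels.
#' @param n grid side length per parameter.
#' @return list of `n^2` entries, each a list with `mask` and `setting`.
#' @export
cannySweep <- function(image, sigma = 1.0, n = 31L) {
  checkImage(image)
  nms <- cannyNonmax(image, sigma)
  m <- max(nms)
  highs <- seq_len(n) / n            # fractions of max magnitude, (0, 1]
  ratios <- (seq_len(n) - 1L) / n    # low = ratio * high, [0, 1)
  out <- vector("list", n * n)
  k <- 0L
  for (hi in highs) for (r in ratios) {
    k <- k + 1L
    mask <- if (m == 0) matrix(0L, nrow(image), ncol(image))
            else cannyHysteresis(nms, r * hi * m, hi * m)
    out[[k]] <- list(mask = mask,
                     setting = sprintf("low=%.4f,high=%.4f", r * hi, hi))
  }
  out
}
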