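# Internal helpers shared across modules: seeded RNG scoping, [0,1] clipping,
# reflect-padded separable convolution and the Gaussian filter bank.

# Run `code` under a fixed seed, restoring the caller's RNG state afterwards so
# package functions never perturb the global stream.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clip01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

checkImage <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(sprintf("'%s' must be a numeric matrix", arg))
  if (any(!is.finite(image)))
    stop(sprintf("'%s' contains non-finite values", arg))
  invisible(image)
}

checkMask <- function(mask, image = NULL, arg = "mask") {
  if (!is.matrix(mask))
    stop(sprintf("'%s' must be a matrix", arg))
  if (!all(mask %in% c(0, 1)))
    stop(sprintf("'%s' must be binary (0/1)", arg))
  if (!is.null(image) && !identical(dim(mask), dim(image)))
    stop(sprintf("'%s' shape does not match the image", arg))
  invisible(mask)
}

# Symmetric (half-sample) reflect indices for a dimension of size n padded by r.
reflectIdx <- function(n, r) {
  if (r >= n) stop("padding radius exceeds image size")
  c(r:1, 1:n, n:(n - r + 1))
}

reflectPad <- function(m, rRow, rCol = rRow) {
  ri <- if (rRow > 0) reflectIdx(nrow(m), rRow) else seq_len(nrow(m))
  ci <- if (rCol > 0) reflectIdx(ncol(m), rCol) else seq_len(ncol(m))
  m[ri, ci, drop = FALSE]
}

# 1-D convolution along rows (kernel slides over the row index) with reflect
# padding, implemented as a shift-and-add over the small kernel support.
convRows <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(m * k)
  p <- reflectPad(m, r, 0L)
  out <- matrix(0, nrow(m), ncol(m))
  for (s in seq_along(k))
    out <- out + k[s] * p[s:(s + nrow(m) - 1L), , drop = FALSE]
  out
}

convCols <- function(m, k) t(convRows(t(m), k))

# Separable convolution: kRow along rows (y), kCol along columns (x).
convSep <- function(m, kRow, kCol) convCols(convRows(m, kRow), kCol)

# Gaussian filter bank. Kernels are sampled on [-r, r] with r = ceil(3*sigma);
# the smoothing kernel is unit-sum, derivative kernels are forced exactly
# DC-free so constant offsets produce a strictly zero response; symmetry makes
# the second-derivative kernel additionally blind to linear ramps.
gaussKernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussDeriv1Kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- -x / sigma^2 * exp(-x^2 / (2 * sigma^2))
  k <- k - mean(k)
  # scale so the (correlation) response to a unit ramp is 1
  k / sum(x * k)
}

gaussDeriv2Kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- (x^2 - sigma^2) / sigma^4 * exp(-x^2 / (2 * sigma^2))
  k <- k - mean(k)
  # scale so response to x^2/2 is 1
  k / sum(x^2 / 2 * k)
}

# One 8-connected binary dilation step.
dilate1 <- function(b) {
  h <- nrow(b); w <- ncol(b)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- b
  out <- b
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out | p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
  }
  out
}

dilateN <- function(b, n) {
  while (n > 0L) { b <- dilate1(b); n <- n - 1L }
  b
}

# Flatten a matrix in row-major pixel scan order (row 1 left-to-right, ...).
rowMajor <- function(m) as.vector(t(m))

# (row, col) pairs for row-major linear indices.
rowMajorCoords <- function(h, w) {
  cbind(row = rep(seq_len(h), each = w), col = rep.int(seq_len(w), h))
}

# Derive a per-stage seed from one global seed; stays below 2^31.
stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) + sum(utf8ToInt(stage)) * 1009) %% 2147483647)
}

# Index of the optimum of a criterion curve; exact ties (plateaus, e.g. runs
# of empty histogram bins) resolve to the middle of the tied run.
criterionOptimum <- function(crit, maximize = TRUE) {
  target <- if (maximize) max(crit, na.rm = TRUE) else min(crit, na.rm = TRUE)
  ties <- which(!is.na(crit) & crit == target)
  ties[(length(ties) + 1L) %/% 2L]
}
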