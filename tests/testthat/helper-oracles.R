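# Brute-force criterion scans, independent of the package implementation.
# Each returns the full set of tied optimal candidate thresholds.

bruteOtsu <- function(image, nLevels = 256L) {
  v <- as.vector(image)
  bin <- pmin(floor(v * nLevels), nLevels - 1L) + 1L
  mids <- (seq_len(nLevels) - 0.5) / nLevels
  crit <- rep(NA_real_, nLevels - 1L)
  for (k in seq_len(nLevels - 1L)) {
    lo <- bin <= k
    if (!any(lo) || all(lo)) next
    w0 <- mean(lo)
    crit[k] <- w0 * (1 - w0) * (mean(mids[bin][lo]) - mean(mids[bin][!lo]))^2
  }
  which(!is.na(crit) & crit == max(crit, na.rm = TRUE)) / nLevels
}

bruteKittler <- function(image, nLevels = 256L) {
  v <- as.vector(image)
  bin <- pmin(floor(v * nLevels), nLevels - 1L) + 1L
  mids <- (seq_len(nLevels) - 0.5) / nLevels
  x <- mids[bin]
  crit <- rep(NA_real_, nLevels - 1L)
  for (k in seq_len(nLevels - 1L)) {
    lo <- bin <= k
    if (!any(lo) || all(lo)) next
    w0 <- mean(lo); w1 <- 1 - w0
    v0 <- mean(x[lo]^2) - mean(x[lo])^2
    v1 <- mean(x[!lo]^2) - mean(x[!lo])^2
    if (v0 <= 1e-12 || v1 <= 1e-12) next
    crit[k] <- 1 + 2 * (w0 * log(sqrt(v0)) + w1 * log(sqrt(v1))) -
      2 * (w0 * log(w0) + w1 * log(w1))
  }
  which(!is.na(crit) & crit == min(crit, na.rm = TRUE)) / nLevels
}
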