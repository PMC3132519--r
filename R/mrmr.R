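# Minimum-redundancy maximum-relevance (mRMR) feature ranking over the 33
# feature columns, with the grouped-property reading: if many positions of one
# patch property rank near the top, the whole 3x3 property belongs in the
# feature vector.

#' Discretise feature columns to three levels
#'
#' Maps each column to levels 1/2/3 by thresholds at mean - k sd and
#' mean + k sd (the convention of the original mRMR formulation for
#' continuous data). Constant columns collapse to the single middle level.
#' Deterministic.
#'
#' @param features a [FeatureMatrix-class] (normalised in typical use).
#' @param k threshold half-width in standard deviations.
#' @return integer matrix of levels, same shape as the feature values.
#' @export
discretizeFeatures <- function(features, k = 0.5) {
  stopifnot(is(features, "FeatureMatrix"))
  x <- features@values
  out <- matrix(2L, nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) {
    mu <- mean(x[, j])
    s <- sqrt(mean((x[, j] - mu)^2))
    if (s == 0) next
    out[x[, j] < mu - k * s, j] <- 1L
    out[x[, j] > mu + k * s, j] <- 3L
  }
  colnames(out) <- colnames(x)
  out
}

#' Empirical mutual information of two discrete vectors
#'
#' Plug-in estimate in bits (base-2 logarithm), with 0 log 0 = 0.
#'
#' @param x,y equal-length vectors of discrete values.
#' @return mutual information in bits (>= 0 up to floating error).
#' @examples
#' mutualInformation(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 1 bit
#' @export
mutualInformation <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  j <- table(x, y) / length(x)
  px <- rowSums(j)
  py <- colSums(j)
  e <- outer(px, py)
  nz <- j > 0
  sum(j[nz] * log2(j[nz] / e[nz]))
}

#' Greedy mRMR feature ranking
#'
#' Ranks features by greedy forward selection: the first pick maximises
#' mutual information with the labels (relevance); each later pick maximises
#' relevance minus the mean mutual information with the already-selected
#' features (the MID, difference form; `quotient = TRUE` switches to the MIQ
#' form relevance / mean-redundancy). Ties break to the lower column index.
#'
#' @param features discrete feature matrix from [discretizeFeatures()].
#' @param labels 0/1 vector, one per row.
#' @param K number of features to rank (1..ncol).
#' @param quotient use the MIQ (quotient) criterion instead of MID.
#' @return a [FeatureRanking-class].
#' @export
mrmrRank <- function(features, labels, K = ncol(features), quotient = FALSE) {
  if (!is.matrix(features)) stop("'features' must be a matrix")
  p <- ncol(features)
  if (K < 1L || K > p) stop("'K' must lie in 1..", p)
  if (length(labels) != nrow(features))
    stop("labels length must equal the number of rows")
  relevance <- vapply(seq_len(p), function(j)
    mutualInformation(features[, j], labels), numeric(1))
  # pairwise feature MI, filled lazily as candidates are compared
  pairMI <- matrix(NA_real_, p, p)
  getMI <- function(a, b) {
    if (is.na(pairMI[a, b])) {
      v <- mutualInformation(features[, a], features[, b])
      pairMI[a, b] <<- v
      pairMI[b, a] <<- v
    }
    pairMI[a, b]
  }
  selected <- integer(0)
  relOut <- numeric(0)
  redOut <- numeric(0)
  remaining <- seq_len(p)
  for (step in seq_len(K)) {
    if (step == 1L) {
      score <- relevance[remaining]
      red <- rep(0, length(remaining))
    } else {
      red <- vapply(remaining, function(j)
        mean(vapply(selected, function(s) getMI(j, s), numeric(1))),
        numeric(1))
      score <- if (quotient) relevance[remaining] / pmax(red, 1e-12)
               else relevance[remaining] - red
    }
    pick <- remaining[which.max(score)]   # which.max ties -> lowest index
    i <- match(pick, remaining)
    selected <- c(selected, pick)
    relOut <- c(relOut, relevance[pick])
    redOut <- c(redOut, red[i])
    remaining <- remaining[-i]
  }
  groups <- if (p == 33L) featureGroups()[selected]
            else rep("feature", length(selected))
  new("FeatureRanking", order = as.integer(selected), relevance = relOut,
      redundancy = redOut, group = groups)
}

#' Grouped relevance of an mRMR ranking
#'
#' Counts how often each feature group (intensity, orientation, statistic)
#' occurs among the top-K ranked features, and applies the grouped-property
#' inclusion rule: a group whose members occupy more than
#' `proportion` of the group's own size within the top K is flagged
#' "include the whole 3x3 property".
#'
#' @param ranking a [FeatureRanking-class] over the 33 standard columns.
#' @param K how many top-ranked features to inspect.
#' @param proportion inclusion-rule fraction of the group size (default 1/2).
#' @return data.frame with columns group, size, topK, flagged.
#' @export
groupedRelevance <- function(ranking, K = 10L, proportion = 0.5) {
  stopifnot(is(ranking, "FeatureRanking"))
  if (K > length(ranking@order)) stop("'K' exceeds the ranking length")
  groups <- featureGroups()
  sizes <- table(factor(groups, levels = c("intensity", "orientation",
                                           "statistic")))
  top <- groups[ranking@order[seq_len(K)]]
  counts <- table(factor(top, levels = names(sizes)))
  data.frame(group = names(sizes),
             size = as.integer(sizes),
             topK = as.integer(counts),
             flagged = as.integer(counts) > proportion * as.integer(sizes),
             row.names = NULL)
}
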