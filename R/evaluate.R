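# Pixel-wise evaluation: confusion counts and accuracy against ground truth,
# ROC construction from threshold/parameter sweeps, and method-comparison
# reports.

#' Pixel-wise confusion counts
#'
#' Counts true/false positives and negatives of a predicted boundary mask
#' against a ground-truth mask (positive class = boundary), optionally
#' excluding a border margin.
#'
#' @param pred predicted 0/1 mask.
#' @param truth ground-truth 0/1 mask of identical shape.
#' @param border number of border rows/columns to exclude (default 0: all
#'   pixels are evaluated).
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(pred, truth, border = 0L) {
  checkMask(pred, arg = "pred")
  checkMask(truth, arg = "truth")
  if (!identical(dim(pred), dim(truth)))
    stop("'pred' and 'truth' shapes differ")
  if (border > 0L) {
    h <- nrow(pred); w <- ncol(pred)
    if (2L * border >= min(h, w)) stop("'border' margin leaves no pixels")
    keep <- (border + 1L):(h - border)
    keepC <- (border + 1L):(w - border)
    pred <- pred[keep, keepC]
    truth <- truth[keep, keepC]
  }
  new("ConfusionCounts",
      tp = sum(pred == 1L & truth == 1L),
      fp = sum(pred == 1L & truth == 0L),
      tn = sum(pred == 0L & truth == 0L),
      fn = sum(pred == 0L & truth == 1L))
}

#' ROC curve from a sweep of masks
#'
#' Computes one (false-positive rate, true-positive rate) point per swept
#' setting, deduplicates identical points and sorts by FPR. Accepts the
#' output of [thresholdSweep()] / [cannySweep()] (entries with `mask` and
#' `setting`) or a plain list of masks.
#'
#' @param sweep list of masks or of lists with elements `mask`, `setting`.
#' @param truth ground-truth 0/1 mask.
#' @param method label stored in the curve.
#' @return a [RocCurve-class].
#' @export
rocFromSweep <- function(sweep, truth, method = "sweep") {
  if (!length(sweep)) stop("empty sweep")
  pts <- lapply(seq_along(sweep), function(i) {
    entry <- sweep[[i]]
    mask <- if (is.list(entry)) entry$mask else entry
    setting <- if (is.list(entry) && !is.null(entry$setting)) entry$setting
               else as.character(i)
    cc <- confusionCounts(mask, truth)
    data.frame(fpr = if (cc@fp + cc@tn > 0) cc@fp / (cc@fp + cc@tn) else 0,
               tpr = if (cc@tp + cc@fn > 0) cc@tp / (cc@tp + cc@fn) else 0,
               setting = setting, stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, pts)
  pts <- pts[!duplicated(pts[, c("fpr", "tpr")]), , drop = FALSE]
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  new("RocCurve", points = pts, method = method)
}

#' Accuracy comparison report across methods and images
#'
#' Applies each method (a function taking an image and returning a 0/1 mask,
#' at its own operating point: a trained SVM, an automatic threshold, a fixed
#' Canny setting) to every image and tabulates the pixel-wise accuracy, plus
#' the per-method mean. A failing method/image cell propagates as NA.
#'
#' @param methods named list of functions `image -> mask`.
#' @param images list of cases, each a list with `image` and `mask`.
#' @return data.frame: one row per method, one accuracy column per image and
#'   a final `mean` column.
#' @export
comparisonReport <- function(methods, images) {
  if (!length(methods) || !length(images))
    stop("need at least one method and one image")
  if (is.null(names(methods)) || any(names(methods) == ""))
    stop("'methods' must be a named list")
  acc <- sapply(images, function(case)
    vapply(methods, function(f)
      tryCatch(accuracy(confusionCounts(f(case$image), case$mask)),
               error = function(e) NA_real_), numeric(1)))
  acc <- matrix(acc, nrow = length(methods),
                dimnames = list(names(methods),
                                paste0("image", seq_along(images))))
  out <- data.frame(method = rownames(acc), acc, row.names = NULL,
                    check.names = FALSE)
  out$mean <- rowMeans(acc, na.rm = TRUE)
  out
}

#' Format a comparison report as fixed-width text
#'
#' @param report data.frame from [comparisonReport()].
#' @return character vector of formatted lines (one header + one per method).
#' @export
formatComparisonReport <- function(report) {
  nums <- vapply(report[-1], function(col) sprintf("%8.2f", col),
                 character(nrow(report)))
  nums <- matrix(nums, nrow = nrow(report))
  header <- sprintf("%-16s%s", "Method",
                    paste(sprintf("%8s", names(report)[-1]), collapse = ""))
  body <- vapply(seq_len(nrow(report)), function(i)
    sprintf("%-16s%s", report$method[i], paste(nums[i, ], collapse = "")),
    character(1))
  c(header, body)
}
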