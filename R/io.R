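# Image and mask file I/O: 8/16-bit grayscale PNG (and TIFF when the tiff
# package is available) read to [0, 1] reals; masks written as {0, 255} PNG
# with boundaries black on white, the display convention for binary
# segmentations of dark boundaries.

isTiffPath <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

#' Read a grayscale image to a [0, 1] intensity matrix
#'
#' PNG (8/16-bit) via the png package; TIFF via the tiff package when
#' installed. Multi-channel images are rejected unless `toGray = TRUE`, in
#' which case Rec. 601 luminance (0.299 R + 0.587 G + 0.114 B) is applied.
#'
#' @param path image file path.
#' @param toGray convert RGB input to luminance instead of failing.
#' @return numeric matrix in [0, 1], indexed [row, col].
#' @export
readGrayImage <- function(path, toGray = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  a <- if (isTiffPath(path)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF files")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L && toGray) {
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else if (dim(a)[3] %in% c(2L, 4L) && !toGray) {
      stop("multi-channel image; pass toGray = TRUE to convert")
    } else if (dim(a)[3] == 1L) {
      a <- a[, , 1]
    } else if (!toGray) {
      stop("multi-channel image; pass toGray = TRUE to convert")
    } else {
      a <- a[, , 1]
    }
  }
  clip01(matrix(as.numeric(a), nrow(a), ncol(a)))
}

#' Write a [0, 1] intensity matrix as a grayscale image
#'
#' 8-bit PNG by default; 16-bit TIFF when the path ends in .tif/.tiff and the
#' tiff package is installed.
#'
#' @param image numeric matrix in [0, 1].
#' @param path output path (.png, .tif or .tiff).
#' @return the path, invisibly.
#' @export
writeGrayImage <- function(image, path) {
  checkImage(image)
  if (isTiffPath(path)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to write TIFF files")
    tiff::writeTIFF(image, path, bits.per.sample = 16L)
  } else {
    png::writePNG(image, path)
  }
  invisible(path)
}

#' Read a boundary mask from a PNG file
#'
#' Non-zero pixels are boundary unless `blackIsBoundary = TRUE` (the export
#' convention of [writeMask()], where boundaries are rendered black on a
#' white background).
#'
#' @param path PNG file path.
#' @param blackIsBoundary interpret black (0) pixels as boundary.
#' @return 0/1 integer matrix, 1 = boundary.
#' @export
readMask <- function(path, blackIsBoundary = TRUE) {
  img <- readGrayImage(path)
  m <- if (blackIsBoundary) img < 0.5 else img >= 0.5
  matrix(as.integer(m), nrow(img), ncol(img))
}

#' Write a boundary mask as a {0, 255} PNG
#'
#' Boundary pixels are rendered black on a white background.
#'
#' @param mask 0/1 matrix, 1 = boundary.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  checkMask(mask)
  png::writePNG(1 - mask, path)
  invisible(path)
}
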