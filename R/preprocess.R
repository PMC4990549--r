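#' Load an image and attach its pixel size
#'
#' Reads a TIFF, PNG or JPEG image, converts RGB to luminance by the
#' unweighted channel mean, rescales intensities to \[0, 1\] by the full
#' range of the stored bit depth, and attaches the pixel size.
#'
#' @param path path to the image file
#' @param pixelSize micrometers per pixel (> 0)
#' @return a [CalibratedImage-class]
#' @examples
#' f <- tempfile(fileext = ".png")
#' EBImage::writeImage(EBImage::Image(matrix(runif(64), 8, 8)), f)
#' img <- loadImage(f, pixelSize = 0.25)
#' @export
loadImage <- function(path, pixelSize) {
  if (length(pixelSize) != 1 || !is.finite(pixelSize) || pixelSize <= 0)
    stop("pixelSize must be a single positive number")
  if (!file.exists(path)) stop("file not found: ", path)
  img <- try(EBImage::readImage(path), silent = TRUE)
  if (inherits(img, "try-error")) stop("cannot decode image: ", path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3) {
    nch <- min(dim(a)[3], 3)        # drop alpha if present
    a <- apply(a[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
  } else if (length(dim(a)) != 2) {
    stop("expected a 2D image, got ", length(dim(a)), " dimensions")
  }
  # EBImage stores x (columns of the file) in dim 1; transpose to row = y
  m <- t(a)
  m <- pmin(pmax(m, 0), 1)
  CalibratedImage(m, pixelSize)
}

#' Pixel size from the endpoints of a scale bar
#'
#' Given the two extreme points of a scale bar of known physical length,
#' returns the pixel size as length over Euclidean pixel distance.
#'
#' @param p1,p2 (x, y) pixel coordinates of the bar endpoints
#' @param barLength physical bar length in micrometers
#' @return micrometers per pixel
#' @examples
#' calibrateFromScaleBar(c(0, 0), c(100, 0), 25)  # 0.25 um/px
#' @export
calibrateFromScaleBar <- function(p1, p2, barLength) {
  if (length(p1) != 2 || length(p2) != 2)
    stop("p1 and p2 must be (x, y) coordinates")
  if (!is.finite(barLength) || barLength <= 0)
    stop("barLength must be > 0")
  d <- sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
  if (d == 0) stop("scale bar endpoints coincide")
  barLength / d
}

#' Pre-processing options
#'
#' @param invert complement intensities (v -> 1 - v), used to make axons
#'   darker than myelin when the native contrast is reversed
#' @param smooth 3 x 3 averaging filter with edge replication
#' @param histEq global histogram equalization to a uniform target over
#'   256 bins
#' @param deconv accepted for parameter-file compatibility; currently a
#'   no-op
#' @return a named list of flags
#' @export
preprocessOptions <- function(invert = FALSE, smooth = FALSE,
                              histEq = FALSE, deconv = FALSE) {
  list(invert = isTRUE(invert), smooth = isTRUE(smooth),
       histEq = isTRUE(histEq), deconv = isTRUE(deconv))
}

#' Pre-process a calibrated image
#'
#' Applies, in fixed order: intensity inversion, 3 x 3 mean filtering
#' (edge replication), and global 256-bin histogram equalization.
#' Inversion comes first so that all later intensity features see the
#' dark-axon convention; equalization comes last to maximize contrast
#' for thresholding.  With all flags FALSE the image is returned
#' unchanged.  The pixel size is never altered.
#'
#' @param img a [CalibratedImage-class]
#' @param options list of flags from [preprocessOptions] (or the
#'   `preprocess` slot of [SegParameters-class])
#' @return a [CalibratedImage-class]
#' @export
preprocessImage <- function(img, options = preprocessOptions()) {
  stopifnot(is(img, "CalibratedImage"))
  m <- img@intensities
  if (isTRUE(options$invert)) m <- 1 - m
  if (isTRUE(options$smooth)) {
    m <- EBImage::filter2(m, matrix(1 / 9, 3, 3), boundary = "replicate")
    m <- pmin(pmax(m, 0), 1)
  }
  if (isTRUE(options$histEq) && diff(range(m)) > 0) {
    m <- EBImage::equalize(m, range = c(0, 1), levels = 256)
    m <- pmin(pmax(m, 0), 1)
  }
  CalibratedImage(m, img@pixelSize)
}

#' Write a CalibratedImage (or mask) to an image file
#'
#' @param x a [CalibratedImage-class], numeric matrix in \[0, 1\], or
#'   integer label matrix (written as 16-bit when the format allows)
#' @param path output path; format from the file extension
#' @return invisibly, the path
#' @export
writeImageFile <- function(x, path) {
  m <- if (is(x, "CalibratedImage")) x@intensities else x
  if (is.integer(m) || max(m) > 1) m <- m / max(max(m), 1)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    EBImage::writeImage(EBImage::Image(t(m)), path, bits.per.sample = 16L)
  else
    EBImage::writeImage(EBImage::Image(t(m)), path)
  invisible(path)
}
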