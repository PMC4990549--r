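#' @include AllGenerics.R
NULL

#' CalibratedImage: a 2D intensity field with physical pixel size
#'
#' Container for a single-channel image normalized to \[0, 1\] together
#' with its isotropic pixel size in micrometers per pixel.  The matrix
#' is stored row = y, column = x; point coordinates throughout the
#' package are (x, y) in pixel units.
#'
#' @slot intensities numeric matrix with values in \[0, 1\], at least 2 x 2
#' @slot pixelSize micrometers per pixel, > 0
#'
#' @examples
#' img <- CalibratedImage(matrix(runif(64), 8, 8), pixelSize = 0.25)
#' pixelSize(img)
#' @aliases intensities pixelSize
#' @export
setClass("CalibratedImage",
         representation(intensities = "matrix", pixelSize = "numeric"))

setValidity("CalibratedImage", function(object) {
  m <- object@intensities
  if (!is.numeric(m)) return("intensities must be a numeric matrix")
  if (nrow(m) < 2 || ncol(m) < 2) return("image must be at least 2 x 2")
  if (anyNA(m) || any(!is.finite(m))) return("intensities must be finite")
  if (min(m) < 0 || max(m) > 1) return("intensities must lie in [0, 1]")
  p <- object@pixelSize
  if (length(p) != 1 || !is.finite(p) || p <= 0)
    return("pixelSize must be a single positive number")
  TRUE
})

#' @param intensities numeric matrix in \[0, 1\]
#' @param pixelSize micrometers per pixel
#' @rdname CalibratedImage-class
#' @export
CalibratedImage <- function(intensities, pixelSize) {
  new("CalibratedImage", intensities = intensities,
      pixelSize = as.numeric(pixelSize))
}

#' @rdname CalibratedImage-class
#' @export
setMethod("intensities", "CalibratedImage", function(x) x@intensities)

#' @rdname CalibratedImage-class
#' @export
setMethod("pixelSize", "CalibratedImage", function(x) x@pixelSize)

#' @rdname CalibratedImage-class
#' @export
setMethod("dim", "CalibratedImage", function(x) dim(x@intensities))

setMethod("show", "CalibratedImage", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("CalibratedImage: %d x %d px, %.4g um/px (%.4g x %.4g um)\n",
              d[1], d[2], object@pixelSize,
              d[1] * object@pixelSize, d[2] * object@pixelSize))
  cat(sprintf("  intensity range [%.3f, %.3f]\n",
              min(object@intensities), max(object@intensities)))
})

#' DAClassifier: Gaussian discriminant over object features
#'
#' A two-class generative Gaussian classifier (linear: shared pooled
#' covariance; quadratic: per-class covariances).  The discriminant
#' score is the log-likelihood ratio of the true-axon class over the
#' false class, plus the log prior ratio; objects scoring at or above
#' `threshold` are accepted.
#'
#' @slot kind "linear" or "quadratic"
#' @slot features character vector naming the feature columns used
#' @slot meanTrue,meanFalse class mean vectors
#' @slot covTrue,covFalse class covariance matrices (equal for linear),
#'   ridge-regularized to be symmetric positive-definite
#' @slot priors length-2 numeric (true, false), summing to 1
#' @slot threshold operating threshold on the discriminant score
#' @export
setClass("DAClassifier",
         representation(kind = "character", features = "character",
                        meanTrue = "numeric", meanFalse = "numeric",
                        covTrue = "matrix", covFalse = "matrix",
                        priors = "numeric", threshold = "numeric"))

setValidity("DAClassifier", function(object) {
  if (!object@kind %in% c("linear", "quadratic"))
    return("kind must be 'linear' or 'quadratic'")
  d <- length(object@meanTrue)
  if (length(object@meanFalse) != d) return("class means differ in length")
  if (!all(dim(object@covTrue) == d) || !all(dim(object@covFalse) == d))
    return("covariance dimensions do not match the means")
  for (S in list(object@covTrue, object@covFalse)) {
    if (max(abs(S - t(S))) > 1e-8) return("covariance not symmetric")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return("covariance not positive-definite")
  }
  if (length(object@priors) != 2 || abs(sum(object@priors) - 1) > 1e-8 ||
      any(object@priors <= 0))
    return("priors must be two positive numbers summing to 1")
  TRUE
})

setMethod("show", "DAClassifier", function(object) {
  cat(sprintf("DAClassifier (%s): %d features [%s]\n", object@kind,
              length(object@features), paste(object@features, collapse = ", ")))
  cat(sprintf("  priors (true, false) = (%.3f, %.3f); threshold = %s\n",
              object@priors[1], object@priors[2],
              ifelse(is.na(object@threshold), "unset",
                     sprintf("%.4f", object@threshold))))
})

#' SegParameters: the complete, serializable segmentation parameter set
#'
#' All tunable parameters of the pipeline, so that a configuration
#' established on a cropped region can be re-applied to other images of
#' similar contrast.  Serialize with [writeSegParameters] /
#' [readSegParameters].
#'
#' @slot pixelSize micrometers per pixel
#' @slot preprocess list with logical flags `invert`, `smooth`,
#'   `histEq`, `deconv` (deconvolution is accepted in the schema but is
#'   a no-op)
#' @slot extendedMin two extended-minima depth thresholds h1, h2 on the
#'   \[0, 1\] intensity scale; the candidate mask is the pixel-wise OR of
#'   the two single-threshold detections
#' @slot priorFilters list `minSize` (um^2), `solidityMin`,
#'   `ellipticityMin`; objects below any threshold are rejected
#'   (thresholds are inclusive: >= keeps)
#' @slot classifier an optional [DAClassifier-class] (or NULL)
#' @slot myelin list of myelin segmentation controls: `nAngles` (number
#'   of angular samples), `nRadii` (radial samples; NA = one per pixel),
#'   `rmaxFactor` (outer sampling radius as a multiple of the candidate
#'   equivalent radius), `maxStep` (max radial index change per angular
#'   step), `smoothWindow` (circular moving-average window on the
#'   boundary radii), `thicknessTol` (tolerated fractional deviation of
#'   per-angle thickness from the median), `gRatioRange` (enforced
#'   g-ratio bounds)
#' @slot blockSize block side for full-image processing, px
#' @slot overlapFraction fractional overlap between adjacent blocks
#' @slot edgeMargin distance from the image border (um) within which
#'   segmented fibers are discarded as potentially incomplete
#' @export
setClass("SegParameters",
         representation(pixelSize = "numeric", preprocess = "list",
                        extendedMin = "numeric", priorFilters = "list",
                        classifier = "ANY", myelin = "list",
                        blockSize = "numeric", overlapFraction = "numeric",
                        edgeMargin = "numeric"))

setValidity("SegParameters", function(object) {
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  if (length(object@extendedMin) != 2 ||
      any(object@extendedMin < 0) || any(object@extendedMin > 1))
    return("extendedMin must be two thresholds in [0, 1]")
  p <- object@priorFilters
  if (p$minSize < 0) return("minSize must be >= 0")
  if (p$solidityMin < 0 || p$solidityMin > 1 ||
      p$ellipticityMin < 0 || p$ellipticityMin > 1)
    return("solidity/ellipticity thresholds must lie in [0, 1]")
  if (!is.null(object@classifier) && !is(object@classifier, "DAClassifier"))
    return("classifier must be a DAClassifier or NULL")
  if (object@blockSize <= 0) return("blockSize must be > 0")
  if (object@overlapFraction < 0 || object@overlapFraction >= 1)
    return("overlapFraction must lie in [0, 1)")
  if (object@edgeMargin < 0) return("edgeMargin must be >= 0")
  m <- object@myelin
  need <- c("nAngles", "rmaxFactor", "maxStep", "smoothWindow",
            "thicknessTol", "gRatioRange")
  if (!all(need %in% names(m))) return("incomplete myelin configuration")
  if (m$nAngles < 8) return("nAngles must be >= 8")
  TRUE
})

#' @param pixelSize micrometers per pixel
#' @param invert,smooth,histEq,deconv pre-processing flags
#' @param extendedMin two detection thresholds in \[0, 1\]
#' @param minSize,solidityMin,ellipticityMin prior screening thresholds
#' @param classifier optional [DAClassifier-class]
#' @param nAngles,nRadii,rmaxFactor,maxStep,smoothWindow,thicknessTol,gRatioRange
#'   myelin segmentation controls (see slots)
#' @param blockSize,overlapFraction,edgeMargin full-image controls
#' @rdname SegParameters-class
#' @export
segParameters <- function(pixelSize,
                          invert = FALSE, smooth = FALSE, histEq = FALSE,
                          deconv = FALSE,
                          extendedMin = c(0.15, 0.3),
                          minSize = 0.2, solidityMin = 0.6,
                          ellipticityMin = 0.3,
                          classifier = NULL,
                          nAngles = 72L, nRadii = NA_integer_,
                          rmaxFactor = 3, maxStep = 1L, smoothWindow = 5L,
                          thicknessTol = 0.5, gRatioRange = c(0.4, 1),
                          blockSize = 512L, overlapFraction = 0.2,
                          edgeMargin = 2) {
  new("SegParameters", pixelSize = as.numeric(pixelSize),
      preprocess = list(invert = invert, smooth = smooth, histEq = histEq,
                        deconv = deconv),
      extendedMin = as.numeric(extendedMin),
      priorFilters = list(minSize = minSize, solidityMin = solidityMin,
                          ellipticityMin = ellipticityMin),
      classifier = classifier,
      myelin = list(nAngles = as.integer(nAngles),
                    nRadii = as.integer(nRadii),
                    rmaxFactor = rmaxFactor, maxStep = as.integer(maxStep),
                    smoothWindow = as.integer(smoothWindow),
                    thicknessTol = thicknessTol,
                    gRatioRange = as.numeric(gRatioRange)),
      blockSize = as.numeric(blockSize),
      overlapFraction = overlapFraction, edgeMargin = edgeMargin)
}

setMethod("show", "SegParameters", function(object) {
  cat("SegParameters\n")
  cat(sprintf("  pixelSize: %.4g um/px\n", object@pixelSize))
  pp <- object@preprocess
  cat(sprintf("  preprocess: invert=%s smooth=%s histEq=%s\n",
              pp$invert, pp$smooth, pp$histEq))
  cat(sprintf("  extended minima h = (%.4f, %.4f)\n",
              object@extendedMin[1], object@extendedMin[2]))
  pf <- object@priorFilters
  cat(sprintf("  priors: minSize=%.4g um^2, solidity>=%.2f, ellipticity>=%.2f\n",
              pf$minSize, pf$solidityMin, pf$ellipticityMin))
  cat(sprintf("  classifier: %s\n",
              if (is.null(object@classifier)) "none" else object@classifier@kind))
  cat(sprintf("  blocks: %d px, overlap %.2f, edge margin %.2f um\n",
              as.integer(object@blockSize), object@overlapFraction,
              object@edgeMargin))
})

#' AxonList: per-fiber morphometric records with pixel masks
#'
#' The central result container: one record per myelinated fiber with
#' its centroid, areas, equivalent diameters, g-ratio and myelin
#' thickness, plus the axon and myelin pixel masks (linear indices into
#' the image matrix).
#'
#' @slot records data.frame, one row per fiber (see [buildAxonList])
#' @slot axonMasks,myelinMasks lists of integer vectors of linear pixel
#'   indices, parallel to `records`
#' @slot pixelSize micrometers per pixel
#' @slot imageDim image dimensions (rows, cols)
#' @aliases axonRecords axonMasks myelinMasks
#' @export
setClass("AxonList",
         representation(records = "data.frame", axonMasks = "list",
                        myelinMasks = "list", pixelSize = "numeric",
                        imageDim = "integer"))

setValidity("AxonList", function(object) {
  n <- nrow(object@records)
  if (length(object@axonMasks) != n || length(object@myelinMasks) != n)
    return("mask lists must be parallel to records")
  if (n > 0) {
    r <- object@records
    need <- c("axonId", "x", "y", "axonAreaPx", "axonAreaUm2",
              "myelinAreaPx", "myelinAreaUm2", "axonEquivDiameter",
              "fiberEquivDiameter", "gRatio", "myelinThickness")
    if (!all(need %in% names(r))) return("missing record columns")
    if (any(r$gRatio <= 0 | r$gRatio > 1 + 1e-9))
      return("gRatio must lie in (0, 1]")
    if (any(r$fiberEquivDiameter < r$axonEquivDiameter - 1e-9))
      return("fiber diameter must be >= axon diameter")
  }
  TRUE
})

#' @rdname AxonList-class
#' @export
setMethod("axonRecords", "AxonList", function(x) x@records)

#' @rdname AxonList-class
#' @export
setMethod("axonMasks", "AxonList", function(x) x@axonMasks)

#' @rdname AxonList-class
#' @export
setMethod("myelinMasks", "AxonList", function(x) x@myelinMasks)

#' @rdname AxonList-class
#' @export
setMethod("pixelSize", "AxonList", function(x) x@pixelSize)

#' @rdname AxonList-class
#' @export
setMethod("length", "AxonList", function(x) nrow(x@records))

#' @rdname AxonList-class
#' @param row.names,optional,... passed on conventionally (ignored)
#' @export
setMethod("as.data.frame", "AxonList",
          function(x, row.names = NULL, optional = FALSE, ...) x@records)

setMethod("show", "AxonList", function(object) {
  n <- nrow(object@records)
  cat(sprintf("AxonList: %d myelinated fiber(s), %d x %d px image, %.4g um/px\n",
              n, object@imageDim[1], object@imageDim[2], object@pixelSize))
  if (n > 0) {
    r <- object@records
    cat(sprintf("  axon diameter: %.2f-%.2f um (median %.2f)\n",
                min(r$axonEquivDiameter), max(r$axonEquivDiameter),
                median(r$axonEquivDiameter)))
    cat(sprintf("  g-ratio: %.3f-%.3f (median %.3f)\n",
                min(r$gRatio), max(r$gRatio), median(r$gRatio)))
  }
})

#' PhantomGroundTruth: a synthetic nerve section with exact geometry
#'
#' Output of [generatePhantom]: the rendered image, per-fiber analytic
#' records (exact diameters and g-ratios as drawn), and axon/myelin
#' label maps consistent with the rasterized fibers.
#'
#' @slot image a [CalibratedImage-class]
#' @slot records data.frame of analytic per-fiber geometry
#' @slot axonLabels,myelinLabels integer label maps (0 = background)
#' @slot spec the generating specification (list)
#' @export
setClass("PhantomGroundTruth",
         representation(image = "CalibratedImage", records = "data.frame",
                        axonLabels = "matrix", myelinLabels = "matrix",
                        spec = "list"))

setMethod("show", "PhantomGroundTruth", function(object) {
  d <- dim(object@image)
  cat(sprintf("PhantomGroundTruth: %d fiber(s) in %d x %d px (%.4g um/px)\n",
              nrow(object@records), d[1], d[2], pixelSize(object@image)))
})

#' AffineTransform2D: a 2D affine map between pixel coordinate frames
#'
#' Maps source (x, y) coordinates to target coordinates as
#' `A %*% c(x, y) + t`.
#'
#' @slot linear non-singular 2 x 2 matrix
#' @slot translation length-2 numeric
#' @aliases applyAffine
#' @export
setClass("AffineTransform2D",
         representation(linear = "matrix", translation = "numeric"))

setValidity("AffineTransform2D", function(object) {
  if (!all(dim(object@linear) == 2)) return("linear part must be 2 x 2")
  if (abs(det(object@linear)) < 1e-12) return("linear part is singular")
  if (length(object@translation) != 2) return("translation must be length 2")
  TRUE
})

#' @rdname AffineTransform2D-class
#' @export
setMethod("applyAffine", "AffineTransform2D", function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 2)
  t(transform@linear %*% t(points) + transform@translation)
})

setMethod("show", "AffineTransform2D", function(object) {
  cat("AffineTransform2D\n  linear:\n")
  print(round(object@linear, 6))
  cat(sprintf("  translation: (%.4g, %.4g)\n",
              object@translation[1], object@translation[2]))
})
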