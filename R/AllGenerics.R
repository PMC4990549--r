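#' @rdname CalibratedImage-class
#' @param x object
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname CalibratedImage-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname AxonList-class
#' @export
setGeneric("axonRecords", function(x) standardGeneric("axonRecords"))

#' @rdname AxonList-class
#' @export
setGeneric("axonMasks", function(x) standardGeneric("axonMasks"))

#' @rdname AxonList-class
#' @export
setGeneric("myelinMasks", function(x) standardGeneric("myelinMasks"))

#' @rdname AffineTransform2D-class
#' @param transform an AffineTransform2D
#' @param points numeric n x 2 matrix of (x, y) coordinates
#' @export
setGeneric("applyAffine", function(transform, points) standardGeneric("applyAffine"))
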