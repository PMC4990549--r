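#' Least-squares affine transform from landmark pairs
#'
#' Finds the 2D affine map minimizing the summed squared residuals
#' `||A s + t - d||^2` over the landmark pairs; with exactly three
#' non-collinear pairs the fit is exact.
#'
#' @param src,dst numeric n x 2 matrices of (x, y) landmark
#'   coordinates, n >= 3
#' @return an [AffineTransform2D-class]
#' @export
estimateAffine <- function(src, dst) {
  src <- matrix(as.numeric(src), ncol = 2)
  dst <- matrix(as.numeric(dst), ncol = 2)
  if (nrow(src) < 3 || nrow(src) != nrow(dst))
    stop("need at least 3 landmark pairs")
  X <- cbind(src, 1)
  if (qr(X)$rank < 3) stop("landmarks are collinear; affine fit singular")
  beta <- qr.solve(X, dst)   # 3 x 2: rows = (x-coef, y-coef, intercept)
  new("AffineTransform2D", linear = t(beta[1:2, ]),
      translation = as.numeric(beta[3, ]))
}

#' Inverse of an affine transform
#' @param transform an [AffineTransform2D-class]
#' @return an [AffineTransform2D-class]
#' @export
invertAffine <- function(transform) {
  Ai <- solve(transform@linear)
  new("AffineTransform2D", linear = Ai,
      translation = as.numeric(-Ai %*% transform@translation))
}

#' Warp a ROI label mask into the image frame
#'
#' Nearest-neighbor resampling (labels must not be interpolated): each
#' target pixel takes the label at the inverse-mapped source position,
#' 0 outside the source mask.
#'
#' @param mask integer ROI label matrix (0 = outside); an optional
#'   "roiNames" attribute is carried over
#' @param transform [AffineTransform2D-class] mapping mask (x, y)
#'   coordinates to image coordinates
#' @param targetDim target dimensions (rows, cols)
#' @return integer label matrix of dimension targetDim
#' @export
warpMask <- function(mask, transform, targetDim) {
  inv <- invertAffine(transform)
  nr <- targetDim[1]; nc <- targetDim[2]
  tx <- rep(seq_len(nc), each = nr)
  ty <- rep(seq_len(nr), times = nc)
  s <- applyAffine(inv, cbind(tx, ty))
  sx <- round(s[, 1]); sy <- round(s[, 2])
  ok <- sx >= 1 & sx <= ncol(mask) & sy >= 1 & sy <= nrow(mask)
  out <- integer(nr * nc)
  out[ok] <- mask[cbind(sy[ok], sx[ok])]
  dim(out) <- c(nr, nc)
  attr(out, "roiNames") <- attr(mask, "roiNames")
  out
}

#' Read a ROI mask image
#'
#' Integer-label masks are read directly (PNG/TIFF, value = ROI id).
#' RGB masks are decoded by exact color matching against a color table:
#' a named list of length-3 RGB vectors on the 0-255 scale; ids are
#' assigned in table order.
#'
#' @param path image path
#' @param colorTable optional named list of RGB triplets for RGB masks
#' @return integer label matrix with attribute "roiNames"
#' @export
readRoiMask <- function(path, colorTable = NULL) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) {
    lab <- t(round(a * 255))
    storage.mode(lab) <- "integer"
    attr(lab, "roiNames") <- as.character(sort(unique(lab[lab > 0])))
    return(lab)
  }
  if (is.null(colorTable))
    stop("RGB mask requires a colorTable (name -> RGB 0-255)")
  r <- t(round(a[, , 1] * 255)); g <- t(round(a[, , 2] * 255))
  b <- t(round(a[, , 3] * 255))
  lab <- matrix(0L, nrow(r), ncol(r))
  for (i in seq_along(colorTable)) {
    cc <- colorTable[[i]]
    lab[r == cc[1] & g == cc[2] & b == cc[3]] <- i
  }
  attr(lab, "roiNames") <- names(colorTable)
  lab
}

#' Assign fibers to regions of interest
#'
#' A fiber belongs to the ROI whose label lies under its (rounded)
#' centroid; a centroid outside every ROI leaves the fiber unassigned.
#' Every fiber is assigned to at most one ROI.
#'
#' @param axl an [AxonList-class] in the same frame as `mask`
#' @param mask integer ROI label matrix
#' @return list with one integer vector of axonIds per ROI id (named),
#'   plus `unassigned`
#' @export
assignAxonsToRois <- function(axl, mask) {
  rec <- axonRecords(axl)
  ids <- sort(unique(mask[mask > 0]))
  res <- stats::setNames(rep(list(integer()), length(ids)), as.character(ids))
  unassigned <- integer()
  if (nrow(rec)) {
    ry <- pmin(pmax(round(rec$y), 1), nrow(mask))
    rx <- pmin(pmax(round(rec$x), 1), ncol(mask))
    roi <- mask[cbind(ry, rx)]
    for (i in seq_len(nrow(rec))) {
      if (roi[i] > 0) {
        k <- as.character(roi[i])
        res[[k]] <- c(res[[k]], rec$axonId[i])
      } else unassigned <- c(unassigned, rec$axonId[i])
    }
  }
  c(res, list(unassigned = unassigned))
}

#' Per-ROI morphometric statistics
#'
#' For each ROI: fiber count, mean and standard deviation of axon
#' equivalent diameter, g-ratio and myelin thickness, axon density
#' (count per mm^2 of ROI area), and the axon-diameter histogram over
#' 50 equal-width bins.  A ROI with no fibers reports count 0 and
#' missing moments.
#'
#' @param axl an [AxonList-class]
#' @param assignment list from [assignAxonsToRois]
#' @param mask the ROI label matrix (for areas)
#' @param nBins histogram bin count
#' @return data.frame, one row per ROI; histograms (breaks, counts) in
#'   attribute "histograms"
#' @export
roiStatistics <- function(axl, assignment, mask, nBins = 50L) {
  rec <- axonRecords(axl)
  px <- pixelSize(axl)
  ids <- setdiff(names(assignment), "unassigned")
  hists <- list()
  rows <- lapply(ids, function(k) {
    sel <- rec[rec$axonId %in% assignment[[k]], , drop = FALSE]
    areaMm2 <- sum(mask == as.integer(k)) * px^2 * 1e-6
    n <- nrow(sel)
    if (n > 0) {
      d <- sel$axonEquivDiameter
      br <- seq(min(d), max(d), length.out = nBins + 1)
      if (diff(range(d)) == 0) br <- c(d[1] - 0.5, d[1] + 0.5)
      h <- graphics::hist(d, breaks = br, plot = FALSE)
      hists[[k]] <<- list(breaks = h$breaks, counts = h$counts)
    }
    data.frame(
      roi = k, count = n,
      meanDiameter = if (n) mean(sel$axonEquivDiameter) else NA_real_,
      sdDiameter = if (n) .sd0(sel$axonEquivDiameter) else NA_real_,
      meanGRatio = if (n) mean(sel$gRatio) else NA_real_,
      sdGRatio = if (n) .sd0(sel$gRatio) else NA_real_,
      meanThickness = if (n) mean(sel$myelinThickness) else NA_real_,
      sdThickness = if (n) .sd0(sel$myelinThickness) else NA_real_,
      areaMm2 = areaMm2,
      density = if (areaMm2 > 0) n / areaMm2 else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "histograms") <- hists
  out
}
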