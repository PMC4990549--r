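#' Polar unwrapping of an axon neighborhood
#'
#' Samples the image on a polar grid centered on the axon centroid:
#' grid\[i, j\] is the bilinear sample at radius r_i (uniform in
#' (0, rMax\]) and angle theta_j (uniform in \[0, 2 pi)).  Samples
#' falling outside the image are clamped to the nearest pixel and
#' flagged.
#'
#' @param img a [CalibratedImage-class]
#' @param centroid (x, y) pixel coordinates of the axon center
#' @param rMax outer sampling radius in micrometers
#' @param nAngles number of angular samples (>= 8)
#' @param nRadii number of radial samples
#' @return list with `grid` (nRadii x nAngles), `origin`, `dr` (um per
#'   radial step), `angles` (radians), `rMax`, `pixelSize`, `clamped`
#' @export
polarUnwrap <- function(img, centroid, rMax, nAngles = 72L, nRadii) {
  stopifnot(is(img, "CalibratedImage"))
  m <- img@intensities
  px <- img@pixelSize
  if (rMax <= 0) stop("rMax must be > 0")
  if (nAngles < 8) stop("nAngles must be >= 8")
  cx <- centroid[1]; cy <- centroid[2]
  if (cx < 1 || cx > ncol(m) || cy < 1 || cy > nrow(m))
    stop("centroid outside the image")
  dr <- rMax / nRadii
  radii <- seq_len(nRadii) * dr
  angles <- (seq_len(nAngles) - 1) * 2 * pi / nAngles
  rr <- outer(radii / px, sin(angles))   # row offset = y
  cc <- outer(radii / px, cos(angles))   # col offset = x
  v <- .bilinear(m, cy + rr, cx + cc)
  grid <- matrix(v, nRadii, nAngles)
  list(grid = grid, origin = c(x = cx, y = cy), dr = dr, angles = angles,
       rMax = rMax, pixelSize = px, clamped = isTRUE(attr(v, "clamped")))
}

#' Radial Sobel gradient of a polar profile
#'
#' 3 x 3 Sobel derivative along the radial axis of the polar grid;
#' the angular axis wraps circularly and the radial axis replicates its
#' ends.  Positive where intensity increases outward.
#'
#' @param profile list from [polarUnwrap] (or a bare grid matrix,
#'   rows = radii)
#' @return gradient matrix of the same dimensions
#' @export
radialGradient <- function(profile) {
  g <- if (is.list(profile)) profile$grid else profile
  nR <- nrow(g); nA <- ncol(g)
  # circular pad in angle, replicate in radius
  gp <- cbind(g[, nA], g, g[, 1])
  gp <- rbind(gp[1, ], gp, gp[nR, ])
  out <- matrix(0, nR, nA)
  # Sobel kernel (radial derivative): rows -1/0/+1 weighted 1-2-1 in angle
  for (i in seq_len(nR)) {
    below <- gp[i, ]; above <- gp[i + 2, ]
    j <- seq_len(nA) + 1
    out[i, ] <- (above[j - 1] + 2 * above[j] + above[j + 1]) -
      (below[j - 1] + 2 * below[j] + below[j + 1])
  }
  out
}

#' Circularly-closed optimal path across a polar cost grid
#'
#' Chooses one radius index per angle minimizing (mode "minimal") or
#' maximizing (mode "maximal") the summed grid values, with consecutive
#' radii - including the wrap-around pair - differing by at most
#' `maxStep`.  The closure constraint is enforced exactly by solving
#' the dynamic program once per admissible starting radius and keeping
#' the best closed path.  Cost ties resolve toward smaller radii, so a
#' uniform grid yields the constant path at the smallest admissible
#' radius.
#'
#' @param grid numeric matrix, rows = radii, columns = angles
#' @param mode "minimal" or "maximal"
#' @param maxStep maximum radial index change per angular step (>= 0)
#' @param lo,hi optional per-angle admissible radius index bounds
#'   (inclusive; recycled if scalar)
#' @return list with `path` (1-based radius index per angle; NULL if no
#'   admissible closed path exists) and `cost` (total in the original
#'   sign convention; NA on failure)
#' @export
optimalCircularPath <- function(grid, mode = c("minimal", "maximal"),
                                maxStep = 1L, lo = NULL, hi = NULL) {
  mode <- match.arg(mode)
  R <- nrow(grid); A <- ncol(grid)
  if (R < 1 || A < 1) stop("empty grid")
  lo <- as.integer(rep_len(if (is.null(lo)) 1L else lo, A))
  hi <- as.integer(rep_len(if (is.null(hi)) R else hi, A))
  g <- if (mode == "maximal") -grid else grid
  res <- cpp_circular_dp(g, as.integer(maxStep), lo, hi)
  if (is.null(res$path)) return(list(path = NULL, cost = NA_real_))
  cost <- if (mode == "maximal") -res$cost else res$cost
  list(path = res$path, cost = cost)
}

#' Segment the myelin sheath around one axon candidate
#'
#' Unwraps the neighborhood to polar coordinates (outer radius
#' `rmaxFactor` times the candidate equivalent radius), computes radial
#' Sobel gradients, finds the outer myelin border as the circularly
#' closed minimal path (strongest outward-decreasing gradient:
#' myelin-to-background transition) and then the inner border as the
#' maximal path constrained strictly inside the outer one (strongest
#' outward-increasing gradient: axon-to-myelin transition).  Both radius
#' sequences are smoothed by a circular moving average; per-angle
#' thickness is constrained to within `thicknessTol` of the median
#' (violating angles have the inner radius reset to outer minus the
#' median thickness), and the implied g-ratio is clamped into
#' `gRatioRange` by scaling the inner border uniformly.  The two closed
#' polygons are rasterized into axon and myelin pixel masks; the axon
#' mask is the morphological fill of the inner border.
#'
#' @param img a [CalibratedImage-class] (dark axons)
#' @param centroid (x, y) candidate centroid, px
#' @param equivDiameter candidate equivalent diameter, um
#' @param cfg myelin configuration list (the `myelin` slot of
#'   [SegParameters-class])
#' @return a "myelinRing" list with per-angle radii (um), pixel masks
#'   (linear indices), centroid and a NULL `failure`; on failure a list
#'   with a reason code in `failure` ("no_path", "outer_at_min",
#'   "non_annular")
#' @export
segmentMyelin <- function(img, centroid, equivDiameter,
                          cfg = segParameters(pixelSize(img))@myelin) {
  px <- pixelSize(img)
  d <- equivDiameter
  rMax <- cfg$rmaxFactor * d / 2
  nRadii <- cfg$nRadii
  if (is.null(nRadii) || is.na(nRadii)) nRadii <- ceiling(rMax / px)
  nRadii <- max(nRadii, 8L)
  prof <- polarUnwrap(img, centroid, rMax, cfg$nAngles, nRadii)
  grad <- radialGradient(prof)

  fail <- function(code) list(failure = code, centroid = centroid)
  outer <- optimalCircularPath(grad, "minimal", cfg$maxStep)
  if (is.null(outer$path)) return(fail("no_path"))
  if (any(outer$path <= 1)) return(fail("outer_at_min"))
  inner <- optimalCircularPath(grad, "maximal", cfg$maxStep,
                               hi = outer$path - 1L)
  if (is.null(inner$path)) return(fail("no_path"))

  rOut <- .circularSmooth(outer$path * prof$dr, cfg$smoothWindow)
  rIn <- .circularSmooth(inner$path * prof$dr, cfg$smoothWindow)

  # thickness homogeneity: per-angle thickness within thicknessTol of
  # the median; violations keep the (more reliable) outer border
  thick <- rOut - rIn
  medT <- median(thick)
  viol <- abs(thick - medT) > cfg$thicknessTol * medT
  rIn[viol] <- rOut[viol] - medT
  rIn <- pmax(rIn, prof$dr / 2)

  # g-ratio constraint: clamp by scaling the inner border uniformly
  gmin <- cfg$gRatioRange[1]; gmax <- cfg$gRatioRange[2]
  gImpl <- sqrt(sum(rIn^2) / sum(rOut^2))
  if (gImpl < gmin) rIn <- rIn * (gmin / gImpl)
  if (gImpl > gmax) rIn <- rIn * (gmax / gImpl)
  rIn <- pmin(rIn, rOut - prof$dr / 4)
  if (any(rIn <= 0) || any(rIn >= rOut)) return(fail("non_annular"))

  # iterate the clamp on the rasterized masks: radial scaling changes
  # area only approximately on the pixel grid, so re-rasterize until
  # the mask-based g-ratio respects the bound
  for (it in 1:8) {
    masks <- .rasterizeRing(dim(img), centroid, rIn, rOut, prof$angles, px)
    if (length(masks$axon) == 0) return(fail("non_annular"))
    gMask <- sqrt(length(masks$axon) /
                    (length(masks$axon) + length(masks$myelin)))
    if (gMask >= gmin - 1e-9 || all(rIn >= rOut - prof$dr / 3)) break
    rIn <- pmin(rIn * max(gmin / gMask, 1 + 1e-3), rOut - prof$dr / 4)
  }

  list(centroid = centroid, angles = prof$angles, innerRadius = rIn,
       outerRadius = rOut, dr = prof$dr, axonPixels = masks$axon,
       myelinPixels = masks$myelin, failure = NULL)
}

# rasterize the annulus between the closed inner and outer boundary
# polygons: a pixel belongs to the fiber if its polar radius is at most
# the (circularly interpolated) outer boundary radius at its angle
.rasterizeRing <- function(imgDim, centroid, rIn, rOut, angles, px) {
  nr <- imgDim[1]; nc <- imgDim[2]
  cx <- centroid[1]; cy <- centroid[2]
  rpx <- max(rOut) / px + 1.5
  r0 <- max(1, floor(cy - rpx)); r1 <- min(nr, ceiling(cy + rpx))
  c0 <- max(1, floor(cx - rpx)); c1 <- min(nc, ceiling(cx + rpx))
  rows <- r0:r1; cols <- c0:c1
  dy <- rep(rows - cy, times = length(cols))
  dx <- rep(cols - cx, each = length(rows))
  rad <- sqrt(dx^2 + dy^2) * px
  th <- atan2(dy, dx) %% (2 * pi)
  nA <- length(angles)
  step <- 2 * pi / nA
  j0 <- floor(th / step)                 # 0-based lower angle index
  f <- th / step - j0
  j0 <- (j0 %% nA) + 1
  j1 <- (j0 %% nA) + 1
  outI <- rOut[j0] * (1 - f) + rOut[j1] * f
  inI <- rIn[j0] * (1 - f) + rIn[j1] * f
  inFiber <- rad <= outI
  inAxon <- rad <= inI
  lin <- rep((cols - 1) * nr, each = length(rows)) + rep(rows, length(cols))
  list(axon = lin[inAxon], myelin = lin[inFiber & !inAxon])
}

#' Myelin overlap conflict cleaning
#'
#' An axon whose myelin mask shares more than 50% of its area with
#' another axon's myelin mask (evaluated against the original,
#' pre-rejection mask set, in ascending axon order) is rejected.  Exact
#' 50% overlap is kept (the rule is strict).
#'
#' @param rings list of "myelinRing" objects from [segmentMyelin]
#' @param threshold overlap fraction above which a ring is rejected
#' @return the kept rings; rejected indices in attribute "rejected"
#' @export
conflictClean <- function(rings, threshold = 0.5) {
  n <- length(rings)
  if (n <= 1) return(rings)
  masks <- lapply(rings, `[[`, "myelinPixels")
  rejected <- logical(n)
  for (i in seq_len(n)) {
    mi <- masks[[i]]
    if (length(mi) == 0) next
    for (j in seq_len(n)) {
      if (j == i) next
      ov <- sum(mi %in% masks[[j]]) / length(mi)
      if (ov > threshold) { rejected[i] <- TRUE; break }
    }
  }
  out <- rings[!rejected]
  attr(out, "rejected") <- which(rejected)
  out
}

#' Axon mask from a myelin ring (morphological filling)
#'
#' The axon mask is the filled region enclosed by the inner myelin
#' border polygon.
#'
#' @param ring a "myelinRing" from [segmentMyelin]
#' @param imgDim image dimensions (rows, cols)
#' @param px micrometers per pixel
#' @return integer vector of linear pixel indices
#' @export
fillAxon <- function(ring, imgDim, px) {
  if (!is.null(ring$failure)) stop("cannot fill a failed ring")
  m <- .rasterizeRing(imgDim, ring$centroid, ring$innerRadius,
                      ring$outerRadius, ring$angles, px)
  m$axon
}
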