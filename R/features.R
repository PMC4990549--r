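#' Per-object shape features
#'
#' For every labeled object: pixel area (px and um^2), perimeter of the
#' traced outer contour polygon, circularity (4 pi A / P^2), solidity
#' (pixel area over convex-hull area, hull taken over pixel corners so
#' solidity <= 1), ellipticity (minor over major axis of the
#' second-central-moment ellipse), equivalent diameter
#' (pixelSize * sqrt(4 A / pi)) and centroid.
#'
#' The perimeter is the length of the closed polygon through the outer
#' boundary pixel centers (contour tracing), not the raw pixel-edge
#' count, which would bias circularity low for disks.  Objects of fewer
#' than 3 pixels are flagged degenerate and fall back to the pixel-edge
#' perimeter.
#'
#' @param labels integer label map (from [cleanupCandidates])
#' @param pixelSize micrometers per pixel
#' @return data.frame with one row per object
#' @export
shapeFeatures <- function(labels, pixelSize) {
  plist <- .objectPixelList(labels)
  if (length(plist) == 0) stop("label map contains no objects")
  out <- lapply(names(plist), function(kk) {
    k <- as.integer(kk)
    px <- plist[[kk]]
    a <- nrow(px)
    degenerate <- a < 3
    per <- if (degenerate) .pixelEdgePerimeter(px) else .contourPerimeter(labels, k, px)
    if (!degenerate && per == 0) { per <- .pixelEdgePerimeter(px); degenerate <- TRUE }
    hullA <- .cornerHullArea(px)
    mom <- .momentAxes(px)
    data.frame(
      objectId = k,
      areaPx = a,
      areaUm2 = a * pixelSize^2,
      perimeterPx = per,
      circularity = 4 * pi * a / per^2,
      solidity = a / hullA,
      ellipticity = mom$minor / mom$major,
      equivDiameter = pixelSize * sqrt(4 * a / pi),
      x = mean(px[, 2]), y = mean(px[, 1]),
      degenerate = degenerate)
  })
  do.call(rbind, out)
}

# perimeter of the traced outer contour polygon (boundary pixel centers)
.contourPerimeter <- function(labels, k, px) {
  r0 <- min(px[, 1]); r1 <- max(px[, 1])
  c0 <- min(px[, 2]); c1 <- max(px[, 2])
  sub <- matrix(0, r1 - r0 + 3, c1 - c0 + 3)
  sub[cbind(px[, 1] - r0 + 2, px[, 2] - c0 + 2)] <- 1
  oc <- EBImage::ocontour(t(sub))   # EBImage works in (x, y) order
  if (length(oc) == 0) return(0)
  p <- oc[[1]]
  if (nrow(p) < 2) return(0)
  nxt <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  sum(sqrt(rowSums((p - nxt)^2)))
}

# exposed pixel-edge count (fallback perimeter for degenerate objects)
.pixelEdgePerimeter <- function(px) {
  key <- paste(px[, 1], px[, 2])
  adj <- 0L
  for (d in list(c(1, 0), c(0, 1))) {
    nb <- paste(px[, 1] + d[1], px[, 2] + d[2])
    adj <- adj + sum(nb %in% key)
  }
  4 * nrow(px) - 2 * adj
}

# convex area as a pixel count: pixels whose centers lie inside (or on)
# the convex hull polygon of the object's pixel centers, so that the
# object is always a subset and solidity <= 1
.cornerHullArea <- function(px) {
  if (nrow(px) < 3) return(nrow(px))
  h <- grDevices::chull(px[, 2], px[, 1])
  hx <- px[h, 2]; hy <- px[h, 1]
  if (length(h) < 3 || .polyArea(hx, hy) == 0)
    return(nrow(px))                            # degenerate (line/point)
  r0 <- min(px[, 1]); r1 <- max(px[, 1])
  c0 <- min(px[, 2]); c1 <- max(px[, 2])
  gy <- rep(r0:r1, times = c1 - c0 + 1)
  gx <- rep(c0:c1, each = r1 - r0 + 1)
  # convex polygon containment by edge-sign consistency; orientation
  # from the signed shoelace area
  n <- length(hx)
  j <- c(2:n, 1)
  sgn <- sign(sum(hx * hy[j] - hx[j] * hy))
  inside <- rep(TRUE, length(gx))
  for (e in seq_len(n)) {
    cr <- (hx[j[e]] - hx[e]) * (gy - hy[e]) - (hy[j[e]] - hy[e]) * (gx - hx[e])
    inside <- inside & (sgn * cr >= -1e-9)
  }
  sum(inside)
}

# ellipse axes from second central moments; each pixel contributes the
# moment of a unit square (+1/12) so single pixels are well-defined
.momentAxes <- function(px) {
  y <- px[, 1]; x <- px[, 2]
  mu20 <- mean((x - mean(x))^2) + 1 / 12
  mu02 <- mean((y - mean(y))^2) + 1 / 12
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-12)
  list(major = sqrt(l1), minor = sqrt(l2))
}

#' Per-object intensity features
#'
#' The neighborhood of an object is its dilation by a disk of radius 2
#' pixels (pixels at center distance <= 2) minus the object itself.
#' Reported per object: object and neighborhood intensity mean and
#' standard deviation, and contrast = neighborhood mean - object mean.
#' An object whose neighborhood is empty (object fills the image) is
#' flagged and gets contrast 0.
#'
#' @param labels integer label map
#' @param img the [CalibratedImage-class] (or matrix) the labels were
#'   derived from; dimensions must match
#' @return data.frame with one row per object
#' @export
intensityFeatures <- function(labels, img) {
  m <- .asIntensity(img)
  if (!all(dim(m) == dim(labels))) stop("labels and image dimensions differ")
  plist <- .objectPixelList(labels)
  if (length(plist) == 0) stop("label map contains no objects")
  disk <- .diskOffsets(2)
  nr <- nrow(m); nc <- ncol(m)
  out <- lapply(names(plist), function(kk) {
    k <- as.integer(kk)
    px <- plist[[kk]]
    ov <- m[px]
    nb <- .dilateCoords(px, disk, nr, nc)
    nb <- nb[labels[nb] != k]
    flagged <- length(nb) == 0
    nv <- m[nb]
    data.frame(
      objectId = k,
      intensityMean = mean(ov), intensitySd = .sd0(ov),
      neighMean = if (flagged) NA_real_ else mean(nv),
      neighSd = if (flagged) NA_real_ else .sd0(nv),
      contrast = if (flagged) 0 else mean(nv) - mean(ov),
      neighEmpty = flagged)
  })
  do.call(rbind, out)
}

# pixel offsets of a rasterized disk: center distance <= r
.diskOffsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[g$dr^2 + g$dc^2 <= r^2, ])
}

# linear indices of the dilation of the coordinate set by the offsets
.dilateCoords <- function(px, offsets, nr, nc) {
  rr <- outer(px[, 1], offsets[, 1], `+`)
  cc <- outer(px[, 2], offsets[, 2], `+`)
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  unique((cc[ok] - 1) * nr + rr[ok])
}

#' Combined shape and intensity features
#'
#' @inheritParams intensityFeatures
#' @param pixelSize micrometers per pixel; taken from `img` when it is
#'   a [CalibratedImage-class]
#' @return data.frame merging [shapeFeatures] and [intensityFeatures]
#' @export
objectFeatures <- function(labels, img, pixelSize = NULL) {
  if (is.null(pixelSize)) {
    if (!is(img, "CalibratedImage"))
      stop("pixelSize required when img is a bare matrix")
    pixelSize <- img@pixelSize
  }
  merge(shapeFeatures(labels, pixelSize), intensityFeatures(labels, img),
        by = "objectId", sort = TRUE)
}

#' Write a feature table as CSV
#'
#' One row per object with the fixed documented header of
#' [objectFeatures].
#'
#' @param features data.frame from [objectFeatures]
#' @param path output path
#' @return invisibly, the path
#' @export
writeFeaturesCsv <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}
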