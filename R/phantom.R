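#' Specification for a synthetic nerve cross-section phantom
#'
#' The phantom emulates the working contrast of the pipeline: bright
#' myelin annuli around dark axon lumens on an intermediate background
#' (axon < background < myelin), with optional mild ellipticity, solid
#' bright distractor disks (no lumen), Gaussian blur and additive
#' Gaussian noise.  All randomness is driven by a single seed and
#' consumed in a fixed order (diameters, g-ratios, axis ratios,
#' orientations, fiber positions, distractors, noise), so generation is
#' bit-reproducible.
#'
#' @param imageSize image side in pixels (square image)
#' @param pixelSize micrometers per pixel
#' @param nFibers number of myelinated fibers
#' @param diameterDist axon-diameter distribution (um): list with
#'   `dist` = "gamma" (shape, scale), "uniform" (min, max) or
#'   "constant" (value), optionally truncated by `min`/`max`
#' @param gRatioDist g-ratio distribution, truncated to \[0.4, 1\]:
#'   same forms as `diameterDist`
#' @param intensities named numeric (axon, background, myelin) in
#'   \[0, 1\], ordered axon < background < myelin
#' @param blurSigma Gaussian blur standard deviation, px (0 = none)
#' @param noiseSigma additive Gaussian noise standard deviation on the
#'   \[0, 1\] intensity scale (0 = none)
#' @param nDistractors number of solid bright disks without a lumen
#' @param minClearance minimum gap between fiber outlines, um
#' @param borderClearance minimum gap between fiber outlines and the
#'   image border, um (keeps complete fibers clear of the edge-margin
#'   discard band)
#' @param maxEccentricity fiber axis ratios are drawn uniformly from
#'   \[1 - maxEccentricity, 1\] (area preserved)
#' @param brightAxons render the complement (bright axons, dark
#'   myelin) to exercise the inversion pre-processing path
#' @param seed integer seed
#' @param fibers optional explicit placement: data.frame with columns
#'   x, y (px), axonDiameter (um), gRatio and optionally axisRatio,
#'   angle; overrides random placement
#' @return a list of class "phantomSpec"
#' @export
phantomSpec <- function(imageSize = 1024L, pixelSize = 0.1, nFibers = 100L,
                        diameterDist = list(dist = "gamma", shape = 3,
                                            scale = 0.7, min = 1, max = 4),
                        gRatioDist = list(dist = "uniform", min = 0.6,
                                          max = 0.8),
                        intensities = c(axon = 0.10, background = 0.45,
                                        myelin = 0.85),
                        blurSigma = 1.5, noiseSigma = 0.05,
                        nDistractors = 10L, minClearance = 1,
                        borderClearance = 3, maxEccentricity = 0.1,
                        brightAxons = FALSE, seed = 1L, fibers = NULL) {
  spec <- list(imageSize = as.integer(imageSize), pixelSize = pixelSize,
               nFibers = as.integer(nFibers), diameterDist = diameterDist,
               gRatioDist = gRatioDist, intensities = intensities,
               blurSigma = blurSigma, noiseSigma = noiseSigma,
               nDistractors = as.integer(nDistractors),
               minClearance = minClearance,
               borderClearance = borderClearance,
               maxEccentricity = maxEccentricity,
               brightAxons = isTRUE(brightAxons), seed = as.integer(seed),
               fibers = fibers)
  if (minClearance < 0) stop("minClearance must be >= 0")
  iv <- intensities
  if (!(iv["axon"] < iv["background"] && iv["background"] < iv["myelin"]))
    stop("intensities must be ordered axon < background < myelin")
  class(spec) <- "phantomSpec"
  spec
}

# draw n values from a named distribution with optional truncation
.sampleDist <- function(dd, n) {
  lo <- dd$min %||% -Inf; hi <- dd$max %||% Inf
  draw <- switch(dd$dist,
    constant = function(k) rep(dd$value, k),
    uniform = function(k) runif(k, dd$min, dd$max),
    gamma = function(k) rgamma(k, shape = dd$shape, scale = dd$scale),
    stop("unknown distribution: ", dd$dist))
  if (dd$dist %in% c("constant", "uniform")) return(draw(n))
  out <- numeric(0)
  for (i in 1:100) {
    x <- draw(n * 2)
    out <- c(out, x[x >= lo & x <= hi])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("truncated distribution rejection sampling failed")
}

#' Generate a phantom with exact ground truth
#'
#' Fibers are placed by dart-throwing with pairwise outline clearance
#' of at least `minClearance`; each fiber is drawn as two concentric
#' (optionally mildly elliptical, area-preserving) disks - outer at the
#' myelin intensity, inner at the axon intensity - then distractors,
#' Gaussian blur and clipped Gaussian noise are applied.  The returned
#' records hold the exact analytic geometry (the analytic g-ratio is
#' exactly the generated inner/outer diameter ratio); the label maps
#' are consistent with the rasterized masks.
#'
#' @param spec a [phantomSpec]
#' @return a [PhantomGroundTruth-class]
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  stopifnot(inherits(spec, "phantomSpec"))
  set.seed(spec$seed)
  n <- spec$imageSize
  px <- spec$pixelSize
  iv <- spec$intensities

  if (is.null(spec$fibers) && spec$nFibers == 0) {
    fib <- data.frame(x = numeric(), y = numeric(),
                      axonDiameter = numeric(), gRatio = numeric(),
                      axisRatio = numeric(), angle = numeric())
    placedX <- numeric(0); placedY <- numeric(0); placedA <- numeric(0)
  } else if (is.null(spec$fibers)) {
    nf <- spec$nFibers
    d <- .sampleDist(spec$diameterDist, nf)
    g <- .sampleDist(modifyList(spec$gRatioDist,
                                list(min = max(spec$gRatioDist$min %||% 0.4, 0.4),
                                     max = min(spec$gRatioDist$max %||% 1, 1))),
                     nf)
    q <- if (spec$maxEccentricity > 0)
      runif(nf, 1 - spec$maxEccentricity, 1) else rep(1, nf)
    ang <- runif(nf, 0, 2 * pi)
    fib <- data.frame(x = NA_real_, y = NA_real_, axonDiameter = d,
                      gRatio = g, axisRatio = q, angle = ang)[seq_len(nf), ,
                                                              drop = FALSE]
    # dart-throwing placement, conservative major-semi-axis clearance
    aUm <- (fib$axonDiameter / fib$gRatio) / 2 / sqrt(fib$axisRatio)
    placedX <- numeric(0); placedY <- numeric(0); placedA <- numeric(0)
    for (i in seq_len(nf)) {
      marginPx <- aUm[i] / px + spec$borderClearance / px
      lo <- 1 + marginPx; hi <- n - marginPx
      if (lo >= hi)
        stop("phantom packing infeasible: fiber diameter ",
             "exceeds the image given borderClearance")
      ok <- FALSE
      for (att in seq_len(10000L)) {
        cx <- runif(1, lo, hi); cy <- runif(1, lo, hi)
        if (length(placedX)) {
          sep <- sqrt((placedX - cx)^2 + (placedY - cy)^2) * px
          if (any(sep < placedA + aUm[i] + spec$minClearance)) next
        }
        ok <- TRUE; break
      }
      if (!ok)
        stop("phantom packing failed after 10000 attempts per fiber: ",
             "reduce nFibers or minClearance")
      placedX <- c(placedX, cx); placedY <- c(placedY, cy)
      placedA <- c(placedA, aUm[i])
      fib$x[i] <- cx; fib$y[i] <- cy
    }
  } else {
    fib <- spec$fibers
    if (is.null(fib$axisRatio)) fib$axisRatio <- 1
    if (is.null(fib$angle)) fib$angle <- 0
    placedX <- fib$x; placedY <- fib$y
    placedA <- (fib$axonDiameter / fib$gRatio) / 2 / sqrt(fib$axisRatio)
  }
  nf <- nrow(fib)

  img <- matrix(iv["background"], n, n)
  axonLab <- matrix(0L, n, n)
  myelinLab <- matrix(0L, n, n)
  for (i in seq_len(nf)) {
    rAx <- fib$axonDiameter[i] / 2
    rFib <- rAx / fib$gRatio[i]
    q <- fib$axisRatio[i]; phi <- fib$angle[i]
    ext <- rFib / sqrt(q) / px + 1
    r0 <- max(1, floor(fib$y[i] - ext)); r1 <- min(n, ceiling(fib$y[i] + ext))
    c0 <- max(1, floor(fib$x[i] - ext)); c1 <- min(n, ceiling(fib$x[i] + ext))
    rows <- r0:r1; cols <- c0:c1
    dy <- (rep(rows, times = length(cols)) - fib$y[i]) * px
    dx <- (rep(cols, each = length(rows)) - fib$x[i]) * px
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    rho <- sqrt((u * sqrt(q))^2 + (v / sqrt(q))^2)   # area-preserving
    lin <- rep((cols - 1) * n, each = length(rows)) + rep(rows, length(cols))
    inFib <- rho <= rFib
    inAx <- rho <= rAx
    img[lin[inFib]] <- iv["myelin"]
    img[lin[inAx]] <- iv["axon"]
    myelinLab[lin[inFib & !inAx]] <- i
    axonLab[lin[inAx]] <- i
  }

  # distractors: solid bright disks without a lumen
  if (spec$nDistractors > 0 && is.null(spec$fibers)) {
    for (k in seq_len(spec$nDistractors)) {
      rad <- runif(1, 0.5, 1.5)
      marginPx <- rad / px + spec$borderClearance / px
      for (att in seq_len(10000L)) {
        cx <- runif(1, 1 + marginPx, n - marginPx)
        cy <- runif(1, 1 + marginPx, n - marginPx)
        sep <- sqrt((placedX - cx)^2 + (placedY - cy)^2) * px
        if (all(sep >= placedA + rad + spec$minClearance)) {
          ext <- rad / px + 1
          r0 <- max(1, floor(cy - ext)); r1 <- min(n, ceiling(cy + ext))
          c0 <- max(1, floor(cx - ext)); c1 <- min(n, ceiling(cx + ext))
          rows <- r0:r1; cols <- c0:c1
          dy <- (rep(rows, times = length(cols)) - cy) * px
          dx <- (rep(cols, each = length(rows)) - cx) * px
          lin <- rep((cols - 1) * n, each = length(rows)) +
            rep(rows, length(cols))
          img[lin[sqrt(dx^2 + dy^2) <= rad]] <- iv["myelin"]
          placedX <- c(placedX, cx); placedY <- c(placedY, cy)
          placedA <- c(placedA, rad)
          break
        }
        if (att == 10000L)
          stop("phantom packing failed for distractors: ",
               "reduce nDistractors or minClearance")
      }
    }
  }

  if (spec$blurSigma > 0) {
    img <- EBImage::gblur(img, sigma = spec$blurSigma)
    img <- pmin(pmax(img, 0), 1)
  }
  if (spec$noiseSigma > 0) {
    img <- img + matrix(rnorm(n * n, sd = spec$noiseSigma), n, n)
    img <- pmin(pmax(img, 0), 1)
  }
  if (spec$brightAxons) img <- 1 - img

  axonAreaPx <- tabulate(axonLab[axonLab > 0], nbins = nf)
  myelinAreaPx <- tabulate(myelinLab[myelinLab > 0], nbins = nf)
  rec <- data.frame(
    axonId = seq_len(nf), x = fib$x, y = fib$y,
    axonAreaPx = axonAreaPx, axonAreaUm2 = axonAreaPx * px^2,
    myelinAreaPx = myelinAreaPx, myelinAreaUm2 = myelinAreaPx * px^2,
    axonEquivDiameter = fib$axonDiameter,
    fiberEquivDiameter = fib$axonDiameter / fib$gRatio,
    gRatio = fib$gRatio,
    myelinThickness = (fib$axonDiameter / fib$gRatio - fib$axonDiameter) / 2,
    axisRatio = fib$axisRatio, angle = fib$angle)

  new("PhantomGroundTruth",
      image = CalibratedImage(img, px), records = rec,
      axonLabels = axonLab, myelinLabels = myelinLab,
      spec = unclass(spec))
}

#' Phantom presets mimicking the three imaging contrasts
#'
#' OM (optical microscopy): strong blur, moderate noise - boundaries
#' smear, small fibers blur together.  SEM (scanning electron
#' microscopy): fine pixels, little blur, strong noise.  CARS: axon
#' intensity close to the background intensity, making lumens hard to
#' distinguish from inter-fiber space.
#'
#' @param modality "OM", "SEM" or "CARS"
#' @param ... overrides passed to [phantomSpec]
#' @return a [phantomSpec]
#' @export
phantomPreset <- function(modality = c("OM", "SEM", "CARS"), ...) {
  modality <- match.arg(modality)
  base <- switch(modality,
    OM = list(pixelSize = 0.1, blurSigma = 1.5, noiseSigma = 0.05),
    SEM = list(pixelSize = 0.08, blurSigma = 0.5, noiseSigma = 0.10),
    CARS = list(pixelSize = 0.2, blurSigma = 0.8, noiseSigma = 0.03,
                intensities = c(axon = 0.42, background = 0.45,
                                myelin = 0.85)))
  do.call(phantomSpec, modifyList(base, list(...)))
}

#' Default segmentation parameters for a phantom
#'
#' Convenience: a [SegParameters-class] whose pixel size matches the
#' phantom specification (phantoms already follow the dark-axon
#' convention, so no pre-processing flags are set).
#'
#' @param spec a [phantomSpec]
#' @param ... overrides passed to [segParameters]
#' @return a [SegParameters-class]
#' @export
phantomSegParameters <- function(spec, ...) {
  segParameters(pixelSize = spec$pixelSize, ...)
}
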