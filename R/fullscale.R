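#' Partition an image into overlapping blocks with disjoint cores
#'
#' Window starts advance by stride = round(blockSize * (1 - overlap));
#' the last window is clamped to the image edge.  Each window owns a
#' "core": overlap zones are split at their midpoint, so the cores are
#' pairwise disjoint and cover the image.  A fiber is kept by the block
#' whose core contains its centroid, which de-duplicates the stitching
#' exactly when the overlap exceeds the largest fiber diameter.
#'
#' @param imageDim image dimensions (rows, cols)
#' @param blockSize block side in pixels (>= 2); a block larger than
#'   the image yields a single full-image window
#' @param overlapFraction fractional overlap in \[0, 1)
#' @return data.frame with one row per block: row0/row1, col0/col1
#'   (inclusive window bounds) and coreRow0/coreRow1, coreCol0/coreCol1
#' @export
partitionBlocks <- function(imageDim, blockSize, overlapFraction = 0.2) {
  if (blockSize < 2) stop("blockSize must be >= 2")
  axis <- function(n) {
    if (blockSize >= n)
      return(data.frame(a0 = 1, a1 = n, c0 = 1, c1 = n))
    stride <- max(1, round(blockSize * (1 - overlapFraction)))
    starts <- 1
    while (starts[length(starts)] + blockSize - 1 < n)
      starts <- c(starts, starts[length(starts)] + stride)
    ends <- pmin(starts + blockSize - 1, n)
    k <- length(starts)
    c0 <- numeric(k); c1 <- numeric(k)
    c0[1] <- 1; c1[k] <- n
    if (k > 1) {
      for (i in seq_len(k - 1)) {
        mid <- floor((starts[i + 1] + ends[i]) / 2)
        c1[i] <- mid
        c0[i + 1] <- mid + 1
      }
    }
    data.frame(a0 = starts, a1 = ends, c0 = c0, c1 = c1)
  }
  ra <- axis(imageDim[1]); ca <- axis(imageDim[2])
  g <- expand.grid(ri = seq_len(nrow(ra)), ci = seq_len(nrow(ca)))
  data.frame(row0 = ra$a0[g$ri], row1 = ra$a1[g$ri],
             col0 = ca$a0[g$ci], col1 = ca$a1[g$ci],
             coreRow0 = ra$c0[g$ri], coreRow1 = ra$c1[g$ri],
             coreCol0 = ca$c0[g$ci], coreCol1 = ca$c1[g$ci])
}

#' Segment one (cropped) image
#'
#' The full single-pass pipeline: pre-process, detect candidates by
#' extended minima, morphological cleanup, per-object features, prior
#' screening (and discriminant classification when the parameter set
#' carries a classifier), per-axon myelin segmentation, and conflict
#' cleaning.
#'
#' @param img a [CalibratedImage-class]
#' @param params a [SegParameters-class]
#' @return an [AxonList-class]; the candidate label map is attached as
#'   attribute "candidates" and dropped-axon reason codes as "failures"
#' @export
segmentImage <- function(img, params) {
  stopifnot(is(img, "CalibratedImage"), is(params, "SegParameters"))
  pre <- preprocessImage(img, params@preprocess)
  mask <- detectCandidates(pre, params)
  labels <- cleanupCandidates(mask)
  empty <- buildAxonList(list(), params@pixelSize, dim(img))
  if (max(labels) == 0) return(empty)
  feats <- objectFeatures(labels, pre)
  keep <- applyPriorFilters(feats, params)
  if (!is.null(params@classifier)) {
    f2 <- feats[feats$objectId %in% keep, , drop = FALSE]
    if (nrow(f2)) keep <- classifyDA(params@classifier, f2)
  }
  feats <- feats[feats$objectId %in% keep, , drop = FALSE]
  if (nrow(feats) == 0) return(empty)
  rings <- lapply(seq_len(nrow(feats)), function(i)
    segmentMyelin(pre, c(feats$x[i], feats$y[i]), feats$equivDiameter[i],
                  params@myelin))
  failures <- vapply(rings, function(r) r$failure %||% "", "")
  rings <- Filter(function(r) is.null(r$failure), rings)
  rings <- conflictClean(rings)
  out <- buildAxonList(rings, params@pixelSize, dim(img))
  attr(out, "candidates") <- labels
  attr(out, "failures") <- failures[nzchar(failures)]
  out
}

#' Block-wise segmentation of a full image
#'
#' Partitions the image into overlapping blocks, runs [segmentImage]
#' on each, and stitches: a fiber is kept only if its centroid lies in
#' the block's core (de-duplication by core ownership), and fibers
#' whose mask touches the band within `edgeMargin` micrometers of the
#' full-image border are discarded as potentially incomplete.  Ids are
#' renumbered globally (by centroid position) and all coordinates are
#' in the full-image frame.  Conflict cleaning operates within blocks.
#'
#' @param img a [CalibratedImage-class]
#' @param params a [SegParameters-class]
#' @param blockSize,overlapFraction optional overrides of the
#'   parameter-set values
#' @return an [AxonList-class] in the full-image frame
#' @export
segmentFullImage <- function(img, params, blockSize = params@blockSize,
                             overlapFraction = params@overlapFraction) {
  stopifnot(is(img, "CalibratedImage"), is(params, "SegParameters"))
  d <- dim(img)
  px <- params@pixelSize
  blocks <- partitionBlocks(d, blockSize, overlapFraction)
  nr <- d[1]
  keptRings <- list()
  failedBlocks <- 0L
  for (b in seq_len(nrow(blocks))) {
    bk <- blocks[b, ]
    sub <- CalibratedImage(
      img@intensities[bk$row0:bk$row1, bk$col0:bk$col1, drop = FALSE], px)
    axl <- tryCatch(segmentImage(sub, params), error = function(e) {
      warning("block ", b, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(axl)) { failedBlocks <- failedBlocks + 1L; next }
    rec <- axonRecords(axl)
    if (nrow(rec) == 0) next
    offR <- bk$row0 - 1; offC <- bk$col0 - 1
    nrSub <- bk$row1 - bk$row0 + 1
    for (i in seq_len(nrow(rec))) {
      x <- rec$x[i] + offC; y <- rec$y[i] + offR
      if (y < bk$coreRow0 - 0.5 || y >= bk$coreRow1 + 0.5 ||
          x < bk$coreCol0 - 0.5 || x >= bk$coreCol1 + 0.5) next
      toFull <- function(idx) {
        r <- ((idx - 1) %% nrSub) + 1 + offR
        c <- ((idx - 1) %/% nrSub) + 1 + offC
        (c - 1) * nr + r
      }
      keptRings[[length(keptRings) + 1]] <- list(
        centroid = c(x, y), axonPixels = toFull(axonMasks(axl)[[i]]),
        myelinPixels = toFull(myelinMasks(axl)[[i]]), failure = NULL)
    }
  }
  if (failedBlocks == nrow(blocks)) stop("all blocks failed")
  # edge-margin rule: discard fibers whose mask enters the border band
  if (length(keptRings) && params@edgeMargin > 0) {
    inBand <- vapply(keptRings, function(r) {
      idx <- c(r$axonPixels, r$myelinPixels)
      rr <- ((idx - 1) %% nr) + 1
      cc <- ((idx - 1) %/% nr) + 1
      distPx <- pmin(rr - 1, nr - rr, cc - 1, d[2] - cc)
      any(distPx * px < params@edgeMargin)
    }, TRUE)
    keptRings <- keptRings[!inBand]
  }
  if (length(keptRings)) {
    ord <- order(vapply(keptRings, function(r) r$centroid[2], 0),
                 vapply(keptRings, function(r) r$centroid[1], 0))
    keptRings <- keptRings[ord]
  }
  buildAxonList(keptRings, px, d)
}

#' Serialize segmentation parameters to JSON
#'
#' Writes every slot of the parameter set, including a fitted
#' classifier when present, so a configuration established on one image
#' can be re-applied to another image of similar contrast.
#'
#' @param params a [SegParameters-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeSegParameters <- function(params, path) {
  clf <- params@classifier
  my <- params@myelin
  if (is.na(my$nRadii)) my$nRadii <- NULL   # NA = auto; JSON null
  obj <- list(
    pixelSize = params@pixelSize,
    preprocess = params@preprocess,
    extendedMin = params@extendedMin,
    priorFilters = params@priorFilters,
    myelin = my,
    blockSize = params@blockSize,
    overlapFraction = params@overlapFraction,
    edgeMargin = params@edgeMargin,
    classifier = if (is.null(clf)) NULL else list(
      kind = clf@kind, features = clf@features,
      meanTrue = clf@meanTrue, meanFalse = clf@meanFalse,
      covTrue = clf@covTrue, covFalse = clf@covFalse,
      priors = clf@priors, threshold = clf@threshold))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Read segmentation parameters from JSON
#'
#' @param path a file written by [writeSegParameters]
#' @return a [SegParameters-class]
#' @export
readSegParameters <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  clf <- NULL
  if (!is.null(o$classifier)) {
    co <- o$classifier
    d <- length(co$meanTrue)
    clf <- new("DAClassifier", kind = co$kind, features = co$features,
               meanTrue = as.numeric(co$meanTrue),
               meanFalse = as.numeric(co$meanFalse),
               covTrue = matrix(as.numeric(t(co$covTrue)), d, d,
                                byrow = TRUE),
               covFalse = matrix(as.numeric(t(co$covFalse)), d, d,
                                 byrow = TRUE),
               priors = as.numeric(co$priors),
               threshold = as.numeric(co$threshold))
  }
  segParameters(pixelSize = o$pixelSize,
                invert = o$preprocess$invert, smooth = o$preprocess$smooth,
                histEq = o$preprocess$histEq, deconv = o$preprocess$deconv,
                extendedMin = o$extendedMin,
                minSize = o$priorFilters$minSize,
                solidityMin = o$priorFilters$solidityMin,
                ellipticityMin = o$priorFilters$ellipticityMin,
                classifier = clf,
                nAngles = o$myelin$nAngles,
                nRadii = o$myelin$nRadii %||% NA_integer_,
                rmaxFactor = o$myelin$rmaxFactor,
                maxStep = o$myelin$maxStep,
                smoothWindow = o$myelin$smoothWindow,
                thicknessTol = o$myelin$thicknessTol,
                gRatioRange = o$myelin$gRatioRange,
                blockSize = o$blockSize,
                overlapFraction = o$overlapFraction,
                edgeMargin = o$edgeMargin)
}
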