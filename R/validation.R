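#' Match detected objects to reference objects by centroid
#'
#' A test object is a true positive when its (rounded) centroid falls
#' inside a reference object; each reference object matches at most one
#' test object (the one with the closest centroid; ties go to the lower
#' test id).  Unmatched test objects are false positives; unmatched
#' reference objects are false negatives.
#'
#' @param test,ref integer label maps of identical dimensions
#' @return list with counts TP, FP, FN and a data.frame `pairs`
#'   (testId, refId)
#' @export
matchByCentroid <- function(test, ref) {
  if (!all(dim(test) == dim(ref))) stop("label maps differ in size")
  tc <- .labelCentroids(test)
  rc <- .labelCentroids(ref)
  nT <- nrow(tc); nR <- nrow(rc)
  cand <- data.frame(testId = integer(), refId = integer(), d = numeric())
  if (nT > 0) {
    ry <- pmin(pmax(round(tc$y), 1), nrow(ref))
    rx <- pmin(pmax(round(tc$x), 1), ncol(ref))
    hit <- ref[cbind(ry, rx)]
    for (i in seq_len(nT)) {
      if (hit[i] > 0) {
        j <- match(hit[i], rc$id)
        d <- sqrt((tc$x[i] - rc$x[j])^2 + (tc$y[i] - rc$y[j])^2)
        cand <- rbind(cand, data.frame(testId = tc$id[i], refId = hit[i],
                                       d = d))
      }
    }
  }
  pairs <- data.frame(testId = integer(), refId = integer())
  if (nrow(cand)) {
    cand <- cand[order(cand$refId, cand$d, cand$testId), ]
    pairs <- do.call(rbind, lapply(split(cand, cand$refId), function(g)
      g[1, c("testId", "refId")]))
    rownames(pairs) <- NULL
  }
  TP <- nrow(pairs)
  list(TP = TP, FP = nT - TP, FN = nR - TP, pairs = pairs)
}

.labelCentroids <- function(lab) {
  plist <- .objectPixelList(lab)
  if (length(plist) == 0)
    return(data.frame(id = integer(), x = numeric(), y = numeric()))
  data.frame(id = as.integer(names(plist)),
             x = vapply(plist, function(p) mean(p[, 2]), 0),
             y = vapply(plist, function(p) mean(p[, 1]), 0))
}

#' Detection sensitivity (true positive rate)
#'
#' TP / (TP + FN); NA when no reference objects exist.
#'
#' @param m match result from [matchByCentroid] (or a list with TP, FN)
#' @return sensitivity in \[0, 1\], or NA
#' @export
detectionSensitivity <- function(m) {
  if (m$TP + m$FN == 0) return(NA_real_)
  m$TP / (m$TP + m$FN)
}

#' Detection precision (positive predictive value)
#'
#' TP / (TP + FP); NA when nothing was detected.
#'
#' @param m match result from [matchByCentroid] (or a list with TP, FP)
#' @return precision in \[0, 1\], or NA
#' @export
detectionPrecision <- function(m) {
  if (m$TP + m$FP == 0) return(NA_real_)
  m$TP / (m$TP + m$FP)
}

#' Per-object Dice coefficients and percentiles
#'
#' For each matched pair, D = 2a / (2a + b + c), where a is the count
#' of shared pixels, b the reference-only and c the test-only pixels.
#' Percentiles use linear interpolation between order statistics.
#'
#' @param test,ref integer label maps
#' @param pairs data.frame (testId, refId) from [matchByCentroid]
#' @param probs percentile levels
#' @return list with `dice` (one value per pair, pair order) and
#'   `percentiles`
#' @export
dicePerObject <- function(test, ref, pairs,
                          probs = c(0.1, 0.5, 0.9)) {
  dice <- vapply(seq_len(nrow(pairs)), function(i) {
    ti <- which(test == pairs$testId[i])
    ri <- which(ref == pairs$refId[i])
    a <- sum(ti %in% ri)
    2 * a / (length(ti) + length(ri))
  }, 0)
  list(dice = dice,
       percentiles = if (length(dice))
         quantile(dice, probs = probs, type = 7, names = TRUE)
       else stats::setNames(rep(NA_real_, length(probs)),
                            paste0(probs * 100, "%")))
}

#' Full detection-quality report
#'
#' Centroid matching plus sensitivity, precision and the Dice
#' distribution percentiles, in one call.
#'
#' @param test,ref integer label maps
#' @return list (TP, FP, FN, sensitivity, precision, dice,
#'   dicePercentiles)
#' @export
validateSegmentation <- function(test, ref) {
  m <- matchByCentroid(test, ref)
  d <- dicePerObject(test, ref, m$pairs)
  list(TP = m$TP, FP = m$FP, FN = m$FN, pairs = m$pairs,
       sensitivity = detectionSensitivity(m),
       precision = detectionPrecision(m),
       dice = d$dice, dicePercentiles = d$percentiles)
}
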