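#' Prior screening of candidate objects
#'
#' Keeps objects with area >= `minSize` (um^2) AND solidity >=
#' `solidityMin` AND ellipticity >= `ellipticityMin`.  Thresholds are
#' inclusive.  The size screen removes small debris; the solidity and
#' ellipticity screens remove ragged inter-fiber spaces.
#'
#' @param features data.frame from [objectFeatures] (needs columns
#'   areaUm2, solidity, ellipticity, objectId)
#' @param params a [SegParameters-class] or a list with `minSize`,
#'   `solidityMin`, `ellipticityMin`
#' @return integer vector of kept objectIds
#' @export
applyPriorFilters <- function(features, params) {
  p <- if (is(params, "SegParameters")) params@priorFilters else params
  keep <- features$areaUm2 >= p$minSize &
    features$solidity >= p$solidityMin &
    features$ellipticity >= p$ellipticityMin
  features$objectId[keep]
}

#' Default feature set entering the discriminant
#'
#' Four shape features plus four intensity-derived features.  The
#' neighborhood mean is omitted because it is the sum of contrast and
#' the object mean, which are both included.
#' @export
daFeatureNames <- function() {
  c("circularity", "solidity", "ellipticity", "equivDiameter",
    "intensityMean", "intensitySd", "neighSd", "contrast")
}

#' Fit a Gaussian discriminant (linear or quadratic)
#'
#' Per-class means and covariances by maximum likelihood; the linear
#' kind pools the class covariances.  A ridge term
#' (1e-6 * trace / d on the diagonal) guarantees invertibility on small
#' training crops.  The discriminant score of an object is the
#' log-likelihood ratio of the true class over the false class plus the
#' log prior ratio; equal priors are the default because class balance
#' on a training crop is not informative about the full image.
#'
#' @param x numeric matrix (rows = objects) or data.frame containing
#'   the columns named in `features`
#' @param labels logical (TRUE = true axon) or factor/character with
#'   two levels
#' @param kind "linear" or "quadratic"
#' @param features character vector of feature columns (defaults to the
#'   columns of `x`)
#' @param priors length-2 numeric (true, false)
#' @return a [DAClassifier-class] with threshold 0 (the symmetric
#'   operating point); use [setOperatingPoint] to pick one from a ROC
#' @export
fitDA <- function(x, labels, kind = c("linear", "quadratic"),
                  features = NULL, priors = c(0.5, 0.5)) {
  kind <- match.arg(kind)
  if (is.logical(labels)) lab <- labels
  else {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2) stop("labels must have exactly two classes")
    lab <- as.character(labels) == lv[2]   # alphabetical: TRUE > FALSE
  }
  if (is.data.frame(x)) {
    if (is.null(features)) features <- setdiff(names(x), "objectId")
    x <- as.matrix(x[, features, drop = FALSE])
  } else {
    x <- as.matrix(x)
    if (is.null(features))
      features <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
    colnames(x) <- features
  }
  if (sum(lab) < 2 || sum(!lab) < 2)
    stop("need at least 2 samples in each class")
  d <- ncol(x)
  xt <- x[lab, , drop = FALSE]; xf <- x[!lab, , drop = FALSE]
  mt <- unname(colMeans(xt)); mf <- unname(colMeans(xf))
  ridge <- function(S) unname(S + diag(1e-6 * sum(diag(S)) / d + 1e-12, d))
  if (kind == "linear") {
    St <- cov(xt) * (nrow(xt) - 1); Sf <- cov(xf) * (nrow(xf) - 1)
    Sp <- ridge((St + Sf) / (nrow(x) - 2))
    covT <- covF <- Sp
  } else {
    covT <- ridge(cov(xt) * (nrow(xt) - 1) / nrow(xt))
    covF <- ridge(cov(xf) * (nrow(xf) - 1) / nrow(xf))
  }
  new("DAClassifier", kind = kind, features = features,
      meanTrue = mt, meanFalse = mf, covTrue = covT, covFalse = covF,
      priors = priors / sum(priors), threshold = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discriminant scores (log-likelihood ratio)
#'
#' @param clf a [DAClassifier-class]
#' @param x matrix or data.frame with the classifier's feature columns
#' @return numeric score per row; higher favors the true-axon class
#' @export
daScores <- function(clf, x) {
  if (is.data.frame(x)) x <- as.matrix(x[, clf@features, drop = FALSE])
  x <- as.matrix(x)
  ldn <- function(x, mu, S) {
    ch <- chol(S)
    z <- forwardsolve(t(ch), t(x) - mu)
    -sum(log(diag(ch))) - 0.5 * colSums(z^2)
  }
  ldn(x, clf@meanTrue, clf@covTrue) - ldn(x, clf@meanFalse, clf@covFalse) +
    log(clf@priors[1] / clf@priors[2])
}

#' ROC curve of a fitted discriminant
#'
#' Sweeps the score threshold over every distinct score (plus +Inf),
#' acceptance rule score >= threshold.  Sensitivity = accepted fraction
#' of the true class, specificity = rejected fraction of the false
#' class.  The endpoints (sensitivity 1, specificity 0) and
#' (sensitivity 0, specificity 1) are always included.
#'
#' @inheritParams daScores
#' @param labels logical, TRUE = true axon
#' @return data.frame (threshold, sensitivity, specificity), threshold
#'   ascending so sensitivity is non-increasing
#' @export
rocCurve <- function(clf, x, labels) {
  s <- daScores(clf, x)
  th <- c(sort(unique(s)), Inf)
  sens <- vapply(th, function(t) mean(s[labels] >= t), 0)
  spec <- vapply(th, function(t) mean(s[!labels] < t), 0)
  data.frame(threshold = th, sensitivity = sens, specificity = spec)
}

#' Select a ROC operating point
#'
#' `min_distance` picks the point closest (Euclidean) to the ideal
#' upper-left corner (sensitivity 1, specificity 1);
#' `max_sensitivity` / `max_specificity` pick the extreme point, ties
#' broken by the better other coordinate, then by the lower threshold.
#'
#' @param roc data.frame from [rocCurve]
#' @param rule one of "min_distance", "max_sensitivity",
#'   "max_specificity"
#' @return single-row data.frame (threshold, sensitivity, specificity,
#'   distance)
#' @export
selectOperatingPoint <- function(roc,
                                 rule = c("min_distance", "max_sensitivity",
                                          "max_specificity")) {
  rule <- match.arg(rule)
  if (nrow(roc) == 0) stop("empty ROC")
  d <- sqrt((1 - roc$sensitivity)^2 + (1 - roc$specificity)^2)
  ord <- switch(rule,
    min_distance = order(d, roc$threshold),
    max_sensitivity = order(-roc$sensitivity, -roc$specificity, roc$threshold),
    max_specificity = order(-roc$specificity, -roc$sensitivity, roc$threshold))
  i <- ord[1]
  cbind(roc[i, , drop = FALSE], distance = d[i])
}

#' Set the operating threshold of a classifier
#'
#' @param clf a [DAClassifier-class]
#' @param threshold numeric score threshold, or a single-row data.frame
#'   from [selectOperatingPoint]
#' @return the classifier with its threshold set
#' @export
setOperatingPoint <- function(clf, threshold) {
  if (is.data.frame(threshold)) threshold <- threshold$threshold
  clf@threshold <- as.numeric(threshold)
  clf
}

#' Classify objects with a fitted discriminant
#'
#' Accepts objects whose score is >= the classifier's operating
#' threshold.  Rows with non-finite feature values are rejected with a
#' warning.
#'
#' @inheritParams daScores
#' @param ids optional object ids parallel to the rows of `x` (defaults
#'   to `x$objectId` or the row number)
#' @return ids of accepted objects
#' @export
classifyDA <- function(clf, x, ids = NULL) {
  if (is.null(ids))
    ids <- if (is.data.frame(x) && "objectId" %in% names(x)) x$objectId
           else seq_len(nrow(x))
  xm <- if (is.data.frame(x)) as.matrix(x[, clf@features, drop = FALSE])
        else as.matrix(x)
  bad <- !apply(is.finite(xm), 1, all)
  if (any(bad)) {
    warning(sum(bad), " object(s) with non-finite features rejected")
    xm[bad, ] <- 0   # placeholder; rejected below regardless of score
  }
  s <- daScores(clf, xm)
  accept <- s >= clf@threshold & !bad
  ids[accept]
}
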