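test_that("prior filters keep objects at or above all thresholds", {
  feats <- data.frame(objectId = 1:4, areaUm2 = c(1, 5, 7, 10),
                      solidity = c(0.9, 0.9, 0.9, 0.9),
                      ellipticity = c(0.8, 0.8, 0.8, 0.8))
  p0 <- list(minSize = 0, solidityMin = 0, ellipticityMin = 0)
  expect_equal(applyPriorFilters(feats, p0), 1:4)
  # minimal-size screen at 6.4730 um^2 keeps areas {7, 10}
  p1 <- list(minSize = 6.4730, solidityMin = 0, ellipticityMin = 0)
  expect_equal(applyPriorFilters(feats, p1), 3:4)
  # boundary inclusivity
  feats$solidity[2] <- 0.84
  p2 <- list(minSize = 0, solidityMin = 0.84, ellipticityMin = 0)
  expect_true(2 %in% applyPriorFilters(feats, p2))
})

test_that("linear DA on symmetric 1D classes crosses zero at the midpoint", {
  set.seed(21)
  x <- matrix(c(rnorm(300, -1), rnorm(300, 1)), ncol = 1)
  lab <- rep(c(FALSE, TRUE), each = 300)
  clf <- fitDA(x, lab, "linear")
  s <- daScores(clf, x)
  # the score is monotone in x and changes sign near x = 0
  xs <- matrix(seq(-3, 3, by = 0.1), ncol = 1)
  ss <- daScores(clf, xs)
  expect_false(is.unsorted(ss))
  root <- xs[which.min(abs(ss))]
  expect_lt(abs(root), 0.25)
})

test_that("linearly separable clusters reach training accuracy 1", {
  set.seed(22)
  x <- rbind(matrix(rnorm(60, -4, 0.3), ncol = 2),
             matrix(rnorm(60, 4, 0.3), ncol = 2))
  lab <- rep(c(FALSE, TRUE), each = 30)
  for (kind in c("linear", "quadratic")) {
    clf <- fitDA(x, lab, kind)
    roc <- rocCurve(clf, x, lab)
    op <- selectOperatingPoint(roc, "min_distance")
    expect_equal(op$sensitivity, 1)
    expect_equal(op$specificity, 1)
    acc <- classifyDA(setOperatingPoint(clf, op), x, ids = seq_along(lab))
    expect_setequal(acc, which(lab))
  }
})

test_that("identical class distributions give chance-level ROC area", {
  set.seed(23)
  x <- matrix(rnorm(800), ncol = 2)
  lab <- rep(c(TRUE, FALSE), 200)
  clf <- fitDA(x, lab, "linear")
  roc <- rocCurve(clf, x, lab)
  # trapezoidal AUC over (1 - specificity, sensitivity)
  fpr <- rev(1 - roc$specificity); tpr <- rev(roc$sensitivity)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  expect_gt(auc, 0.4); expect_lt(auc, 0.6)
})

test_that("ROC enumeration matches the worked 4-sample set", {
  # scores {-2,-1,1,2}, labels {F,F,T,T}: 5 distinct operating points
  clf <- fitDA(matrix(c(-2, -1, 1, 2), ncol = 1),
               c(FALSE, FALSE, TRUE, TRUE), "linear")
  s <- daScores(clf, matrix(c(-2, -1, 1, 2), ncol = 1))
  expect_false(is.unsorted(s))  # monotone in the 1D feature
  roc <- rocCurve(clf, matrix(c(-2, -1, 1, 2), ncol = 1),
                  c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(nrow(roc), 5)
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 0))
  expect_true(any(roc$sensitivity == 0 & roc$specificity == 1))
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 1))
  # brute-force sweep oracle: every (sens, spec) pair reachable
  sweep <- unique(t(vapply(c(-Inf, s, Inf), function(t)
    c(mean(s[3:4] >= t), mean(s[1:2] < t)), numeric(2))))
  got <- unique(as.matrix(roc[, c("sensitivity", "specificity")]))
  expect_equal(nrow(got), nrow(sweep))
})

test_that("ROC is a staircase in the threshold", {
  set.seed(24)
  x <- matrix(rnorm(200, rep(c(0, 1), each = 50)), ncol = 2)
  lab <- rep(c(FALSE, TRUE), each = 50)
  roc <- rocCurve(fitDA(x, lab, "quadratic"), x, lab)
  expect_true(all(diff(roc$sensitivity) <= 1e-12))
  expect_true(all(diff(roc$specificity) >= -1e-12))
})

test_that("operating-point rules follow their definitions", {
  roc <- data.frame(threshold = c(-1, 0, 1),
                    sensitivity = c(1, 0.9, 0.2),
                    specificity = c(0, 0.8, 1))
  op <- selectOperatingPoint(roc, "min_distance")
  expect_equal(op$threshold, 0)
  expect_equal(op$distance, sqrt(0.01 + 0.04), tolerance = 1e-12)
  expect_equal(selectOperatingPoint(roc, "max_sensitivity")$threshold, -1)
  expect_equal(selectOperatingPoint(roc, "max_specificity")$threshold, 1)
  # a perfect point is selected with distance 0
  roc2 <- rbind(roc, data.frame(threshold = 0.5, sensitivity = 1,
                                specificity = 1))
  expect_equal(selectOperatingPoint(roc2, "min_distance")$distance, 0)
})

test_that("classification respects extreme thresholds and non-finite rows", {
  set.seed(25)
  x <- matrix(rnorm(40), ncol = 2)
  lab <- rep(c(TRUE, FALSE), 10)
  clf <- fitDA(x, lab, "linear")
  expect_equal(classifyDA(setOperatingPoint(clf, -Inf), x), seq_len(20))
  expect_equal(length(classifyDA(setOperatingPoint(clf, Inf), x)), 0)
  xb <- x; xb[3, 1] <- NaN
  expect_warning(ids <- classifyDA(setOperatingPoint(clf, -Inf), xb),
                 "non-finite")
  expect_false(3 %in% ids)
})

test_that("linear scores are affine and quadratic reduces to linear under equal covariances", {
  set.seed(26)
  x <- matrix(rnorm(200), ncol = 2)
  lab <- rep(c(TRUE, FALSE), each = 50)
  clf <- fitDA(x, lab, "linear")
  # affine: score of midpoint = mean of scores
  a <- x[1:10, ]; b <- x[11:20, ]
  expect_equal(daScores(clf, (a + b) / 2),
               (daScores(clf, a) + daScores(clf, b)) / 2, tolerance = 1e-9)
  # force equal covariances in a quadratic classifier
  q <- fitDA(x, lab, "quadratic")
  q@covTrue <- clf@covTrue; q@covFalse <- clf@covFalse
  expect_equal(daScores(q, x), daScores(clf, x), tolerance = 1e-9)
})

test_that("DA agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(27)
  x <- rbind(matrix(rnorm(100, 0), ncol = 2),
             matrix(rnorm(100, 1.5), ncol = 2))
  colnames(x) <- c("f1", "f2")
  lab <- rep(c(FALSE, TRUE), each = 50)
  clf <- fitDA(x, lab, "linear")
  pred <- daScores(clf, x) >= 0
  ref <- MASS::lda(x, grouping = lab, prior = c(0.5, 0.5))
  refPred <- predict(ref, x)$class == "TRUE"
  expect_gte(mean(pred == refPred), 0.98)
  clfQ <- fitDA(x, lab, "quadratic")
  refQ <- MASS::qda(x, grouping = lab, prior = c(0.5, 0.5))
  expect_gte(mean((daScores(clfQ, x) >= 0) ==
                    (predict(refQ, x)$class == "TRUE")), 0.98)
})

test_that("trained discriminant separates annuli from solid blobs on phantoms", {
  # train on one phantom (annuli = true, distractor-like solid bright
  # blobs do not produce candidates; use shallow fake features instead)
  set.seed(28)
  ph <- smallPhantom(seed = 28)
  pars <- phantomSegParameters(ph@spec)
  pre <- preprocessImage(ph@image, pars@preprocess)
  lab <- cleanupCandidates(detectCandidates(pre, pars))
  feats <- objectFeatures(lab, pre)
  # true axons: low intensity, high contrast; construct a false class
  # with the opposite profile plus shape jitter
  fake <- feats
  fake$intensityMean <- 1 - fake$intensityMean
  fake$contrast <- -fake$contrast
  fake$circularity <- pmax(0.2, fake$circularity - 0.4)
  allF <- rbind(feats, fake)
  labv <- rep(c(TRUE, FALSE), each = nrow(feats))
  clf <- fitDA(allF[, daFeatureNames()], labv, "quadratic")
  roc <- rocCurve(clf, allF[, daFeatureNames()], labv)
  op <- selectOperatingPoint(roc, "min_distance")
  expect_gte(op$sensitivity, 0.95)
  expect_gte(op$specificity, 0.95)
})
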