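test_that("polar unwrapping is exact on constants and near-invariant on rings", {
  img <- CalibratedImage(matrix(0.37, 64, 64), 0.1)
  prof <- polarUnwrap(img, c(32, 32), rMax = 2, nAngles = 16, nRadii = 10)
  expect_true(all(abs(prof$grid - 0.37) < 1e-12))
  expect_equal(dim(prof$grid), c(10L, 16L))
  expect_equal(prof$dr, 0.2)

  # rotationally symmetric ring: angular columns agree up to the
  # bilinear rasterization error of the pixel grid
  img <- annulusImage(256, 0.1, rIn = 4, rOut = 6, blur = 1.5)
  prof <- polarUnwrap(img, c(128.5, 128.5), rMax = 8, nAngles = 36,
                      nRadii = 60)
  spread <- apply(prof$grid, 1, function(v) diff(range(v)))
  expect_lt(max(spread), 0.1)
  profMean <- rowMeans(prof$grid)
  expect_lt(max(apply(prof$grid, 1, stats::sd)), 0.02)

  # a bright ring of known radius peaks at the right radial row
  img <- annulusImage(256, 0.1, rIn = 4, rOut = 6, iAxon = 0.45)  # ring 4-6
  prof <- polarUnwrap(img, c(128.5, 128.5), rMax = 8, nAngles = 36,
                      nRadii = 80)
  rowMean <- rowMeans(prof$grid)
  peak <- prof$dr * which.max(rowMean)
  expect_gt(peak, 4); expect_lt(peak, 6)

  expect_error(polarUnwrap(img, c(-5, 10), 2, 16, 10), "outside")
  expect_error(polarUnwrap(img, c(10, 10), -1, 16, 10), "rMax")
})

test_that("radial Sobel gradient matches hand convolution", {
  # constant grid: zero gradient
  expect_true(all(radialGradient(matrix(0.5, 6, 8)) == 0))
  # linear outward ramp: constant positive gradient in interior rows
  g <- matrix(rep(1:6, 8), 6, 8)
  rg <- radialGradient(g)
  expect_true(all(rg[2:5, ] == 8))     # sobel sum of weights = 8 per unit
  expect_true(all(rg > 0) || all(rg[2:5, ] > 0))
  # random grid vs direct hand convolution with circular angular wrap
  set.seed(31)
  g <- matrix(runif(40), 5, 8)
  rg <- radialGradient(g)
  nR <- 5; nA <- 8
  for (i in c(2, 4)) for (j in c(1, 5, 8)) {
    jm <- ((j - 2) %% nA) + 1; jp <- (j %% nA) + 1
    want <- (g[i + 1, jm] + 2 * g[i + 1, j] + g[i + 1, jp]) -
      (g[i - 1, jm] + 2 * g[i - 1, j] + g[i - 1, jp])
    expect_equal(rg[i, j], want, tolerance = 1e-12)
  }
  # step profile: strongest response adjacent to the step
  g <- matrix(rep(c(0.2, 0.2, 0.2, 0.8, 0.8, 0.8), 8), 6, 8)
  rg <- radialGradient(g)
  expect_true(all(which.max(rg[, 1]) %in% 3:4))
})

test_that("circular DP equals exhaustive enumeration on random grids", {
  set.seed(32)
  for (rep in 1:40) {
    R <- sample(2:4, 1); A <- sample(3:5, 1)
    g <- matrix(runif(R * A), R, A)
    step <- sample(0:2, 1)
    for (mode in c("minimal", "maximal")) {
      got <- optimalCircularPath(g, mode, maxStep = step)
      want <- oracle_circular_path(g, step, maximize = (mode == "maximal"))
      expect_equal(got$cost, want$cost, tolerance = 1e-12)
    }
  }
})

test_that("DP honors ties, constraints and failure cases", {
  # single zero-cost row attracts the whole path
  g <- matrix(1, 4, 6); g[3, ] <- 0
  expect_equal(optimalCircularPath(g, "minimal", 1)$path, rep(3L, 6))
  # uniform grid: constant path at the smallest admissible radius
  expect_equal(optimalCircularPath(matrix(2, 5, 7), "minimal", 1)$path,
               rep(1L, 7))
  # per-angle upper bounds are respected
  g <- matrix(0, 4, 4); g[1:2, ] <- 5
  r <- optimalCircularPath(g, "minimal", 1, hi = c(2, 2, 2, 2))
  expect_true(all(r$path <= 2))
  # infeasible closure: lo/hi force a jump larger than maxStep
  r2 <- optimalCircularPath(matrix(0, 5, 4), "minimal", 0,
                            lo = c(1, 5, 1, 1), hi = c(1, 5, 1, 1))
  expect_null(r2$path)
  expect_true(is.na(r2$cost))
})

test_that("myelin segmentation recovers clean annulus geometry", {
  # lumen diameter 4 um, fiber diameter 6 um (g = 2/3)
  img <- annulusImage(160, 0.1, rIn = 2, rOut = 3, blur = 0.8)
  cfg <- segParameters(0.1)@myelin
  ring <- segmentMyelin(img, c(80.5, 80.5), 4, cfg)
  expect_null(ring$failure)
  # recovered radii within one pixel of truth at every angle
  expect_lt(max(abs(ring$innerRadius - 2)), 0.1 + 1e-9)
  expect_lt(max(abs(ring$outerRadius - 3)), 0.1 + 1e-9)
  expect_true(all(ring$innerRadius < ring$outerRadius))
  # circular continuity of both boundaries
  for (rr in list(ring$innerRadius, ring$outerRadius)) {
    steps <- abs(diff(c(rr, rr[1])))
    expect_lt(max(steps), 3 * ring$dr)
  }
})

test_that("thickness homogeneity repair bounds per-angle deviations", {
  # perturb one angular sector of the myelin
  img <- annulusImage(160, 0.1, rIn = 2, rOut = 3, blur = 0.5)
  m <- intensities(img)
  dy <- rep(seq_len(160), times = 160) - 80.5
  dx <- rep(seq_len(160), each = 160) - 80.5
  ang <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2) * 0.1
  sector <- ang > 0.3 & ang < 0.9 & r > 2.4 & r <= 3
  m[sector] <- 0.45   # erode the outer half of the sheath in one sector
  ring <- segmentMyelin(CalibratedImage(m, 0.1), c(80.5, 80.5), 4,
                        segParameters(0.1)@myelin)
  expect_null(ring$failure)
  thick <- ring$outerRadius - ring$innerRadius
  expect_true(all(abs(thick - median(thick)) <= 0.5 * median(thick) + 1e-9))
})

test_that("g-ratio is clamped into [0.4, 1] for very thick myelin", {
  # inner/outer diameter ratio 0.25: unconstrained solution implies
  # g ~ 0.25, the constraint must pull it up to at least 0.4
  img <- annulusImage(200, 0.1, rIn = 1, rOut = 4, blur = 0.5)
  ring <- segmentMyelin(img, c(100.5, 100.5), 2,
                        segParameters(0.1)@myelin)
  expect_null(ring$failure)
  g <- sqrt(length(ring$axonPixels) /
              (length(ring$axonPixels) + length(ring$myelinPixels)))
  expect_gte(g, 0.4 - 0.01)
  expect_lte(g, 1)
})

test_that("segmentation is equivariant under quarter-turn rotation", {
  img <- annulusImage(128, 0.1, cx = 50, cy = 70, rIn = 1.5, rOut = 2.4,
                      blur = 0.8)
  cfg <- segParameters(0.1)@myelin
  r1 <- segmentMyelin(img, c(50, 70), 3, cfg)
  # rotate the image by 90 degrees (counterclockwise in matrix terms)
  m2 <- t(intensities(img))[, rev(seq_len(128))]
  img2 <- CalibratedImage(m2, 0.1)
  r2 <- segmentMyelin(img2, c(128 + 1 - 70, 50), 3, cfg)
  expect_null(r1$failure); expect_null(r2$failure)
  # radii sequences agree up to a circular shift by a quarter period
  n <- length(r1$outerRadius)
  quarter <- vapply(c(0, n / 4, n / 2, 3 * n / 4), function(s)
    max(abs(r1$outerRadius[((seq_len(n) - 1 + s) %% n) + 1] -
              r2$outerRadius)), 0)
  expect_lt(min(quarter), 2.5 * r1$dr)
  # area-based quantities are rotation-invariant
  expect_equal(length(r2$axonPixels), length(r1$axonPixels),
               tolerance = 0.04 * length(r1$axonPixels))
})

test_that("conflict cleaning rejects on strict majority myelin overlap", {
  # disjoint rings are kept
  rA <- ringFromMasks(1:10, 101:200)
  rB <- ringFromMasks(301:310, 401:500)
  kept <- conflictClean(list(rA, rB))
  expect_equal(length(kept), 2)

  # 60% of A's myelin inside B: A rejected, B kept (B's own share is
  # 60/150 = 40%)
  rA <- ringFromMasks(1:10, 1001:1100)            # 100 px myelin
  rB <- ringFromMasks(11:20, c(1001:1060, 2001:2090))  # 150 px myelin
  kept <- conflictClean(list(rA, rB))
  expect_equal(length(kept), 1)
  expect_equal(attr(kept, "rejected"), 1L)

  # exactly 50%: kept (strictly-greater rule)
  rA <- ringFromMasks(1:10, 1001:1100)
  rB <- ringFromMasks(11:20, c(1001:1050, 2001:2150))
  kept <- conflictClean(list(rA, rB))
  expect_equal(length(kept), 2)
})

test_that("conflict cleaning uses pre-rejection masks in ascending order", {
  # chain: A overlaps B (60%), B overlaps C (60%), C clean.
  # evaluation against the original set rejects both A and B.
  rA <- ringFromMasks(1:2, 1001:1100)
  rB <- ringFromMasks(3:4, c(1001:1060, 3001:3040))
  rC <- ringFromMasks(5:6, c(3001:3060, 5001:5040))
  kept <- conflictClean(list(rA, rB, rC))
  expect_equal(attr(kept, "rejected"), c(1L, 2L))
  # no surviving ring overlaps any other original mask by > 50%
  masks <- list(rA, rB, rC)
  for (k in kept) {
    for (m in masks) {
      ov <- sum(k$myelinPixels %in% m$myelinPixels) / length(k$myelinPixels)
      expect_true(ov <= 0.5 || identical(k$myelinPixels, m$myelinPixels))
    }
  }
})

test_that("axon filling reproduces disk areas and the g = 1 limit", {
  img <- annulusImage(160, 0.1, rIn = 2, rOut = 3, blur = 0.5)
  ring <- segmentMyelin(img, c(80.5, 80.5), 4, segParameters(0.1)@myelin)
  filled <- fillAxon(ring, c(160, 160), 0.1)
  expect_setequal(filled, ring$axonPixels)
  # area of a disk of radius ~2 um = pi * 20^2 px, within the perimeter
  rPx <- mean(ring$innerRadius) / 0.1
  expect_lt(abs(length(filled) - pi * rPx^2), 2 * pi * rPx + 10)
  # inner -> outer limit: myelin mask empties
  ring$innerRadius <- ring$outerRadius
  m <- myelinMorph:::.rasterizeRing(c(160, 160), ring$centroid,
                                    ring$innerRadius, ring$outerRadius,
                                    ring$angles, 0.1)
  expect_equal(length(m$myelin), 0)
  # filled mask vs the analytic lumen disk: Dice >= 0.95
  truth <- which(diskMask(160, 2 / 0.1, 80.5, 80.5))
  a <- sum(filled %in% truth)
  dice <- 2 * a / (length(filled) + length(truth))
  expect_gte(dice, 0.95)
})
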