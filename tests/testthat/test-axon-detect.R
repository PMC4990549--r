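test_that("h-minima transform reproduces hand-traced 1D profiles", {
  p <- matrix(c(5, 2, 5, 1, 5) / 255, nrow = 1)
  expect_equal(hMinimaTransform(p, 0), p)                       # h = 0
  expect_equal(round(hMinimaTransform(p, 3 / 255) * 255),
               matrix(c(5, 5, 5, 4, 5), nrow = 1))
  # constant image: the whole image is one plateau, raised by h as in
  # standard grayscale reconstruction; no structure appears
  const <- matrix(0.3, 4, 4)
  hm <- hMinimaTransform(const, 0.2)
  expect_equal(diff(range(hm)), 0)
  expect_true(all(hm >= const))
  expect_error(hMinimaTransform(p, -0.1), "\\[0, 1\\]")
  # output >= input pointwise
  set.seed(7)
  img <- matrix(runif(64), 8, 8)
  expect_true(all(hMinimaTransform(img, 0.2) >= img - 1 / 255 - 1e-12))
})

test_that("extended minima match hand-traced profiles and ramps", {
  p <- matrix(c(5, 2, 5, 1, 5) / 255, nrow = 1)
  expect_equal(which(extendedMinima(p, 2 / 255)), c(2L, 4L))
  expect_equal(which(extendedMinima(p, 3 / 255)), 4L)
  # strictly increasing ramp: a single connected minimum at the low end
  ramp <- matrix(seq(0, 1, length.out = 16), nrow = 1)
  em <- extendedMinima(ramp, 0.1)
  expect_equal(max(labelComponents(em)), 1)
  expect_true(em[1])
  expect_false(em[16])
})

test_that("extended minima equal the brute-force oracle on random images", {
  set.seed(101)
  for (rep in 1:25) {
    imgInt <- matrix(sample(0:9, 64, replace = TRUE), 8, 8)
    for (h in c(1, 3)) {
      got <- extendedMinima(imgInt / 255, h / 255)
      want <- oracle_extended_minima(imgInt, h)
      expect_identical(got, want)
    }
  }
})

test_that("h-minima is monotone in h and minima count non-increasing", {
  set.seed(55)
  for (rep in 1:5) {
    img <- matrix(sample(0:200, 100, replace = TRUE) / 255, 10, 10)
    h1 <- hMinimaTransform(img, 0.1); h2 <- hMinimaTransform(img, 0.3)
    expect_true(all(h2 >= h1 - 1e-12))
    n1 <- max(labelComponents(extendedMinima(img, 0.1)))
    n2 <- max(labelComponents(extendedMinima(img, 0.3)))
    expect_lte(n2, n1)
  }
})

test_that("two-threshold detection is the OR of single thresholds", {
  set.seed(9)
  img <- matrix(runif(144), 12, 12)
  expect_identical(detectCandidates(img, c(0.2, 0.2)),
                   extendedMinima(img, 0.2))
  both <- detectCandidates(img, c(0.1, 0.3))
  expect_identical(both, extendedMinima(img, 0.1) | extendedMinima(img, 0.3))
})

test_that("dual thresholds recover both deep and shallow lumens", {
  # one myelin disk holding a deep lumen (0.1) and a shallow lumen
  # (0.35), separated by a weak internal wall (0.5): a large h floods
  # the shallow basin over the wall so its marker vanishes; a small h
  # keeps both; the OR of the two masks detects both
  m <- matrix(0.45, 96, 96)
  dy <- rep(1:96, times = 96) - 48; dx <- rep(1:96, each = 96) - 48
  m[sqrt(dx^2 + dy^2) <= 30] <- 0.85                    # myelin disk
  m[dy > -3 & dy < 3 & abs(dx) <= 12] <- 0.5            # weak wall band
  m[sqrt((dx + 12)^2 + dy^2) <= 8] <- 0.10              # deep lumen
  m[sqrt((dx - 12)^2 + dy^2) <= 8] <- 0.35              # shallow lumen
  img <- CalibratedImage(m, 0.1)
  nObj <- function(mask) max(cleanupCandidates(mask))
  low <- nObj(extendedMinima(img, 0.05))
  high <- nObj(extendedMinima(img, 0.3))
  merged <- nObj(detectCandidates(img, c(0.05, 0.3)))
  expect_equal(low, 2)     # small h sees both basins
  expect_equal(high, 1)    # large h floods the shallow basin away
  expect_equal(merged, 2)  # the OR keeps both
})

test_that("cleanup removes specks, fills holes, clears the border", {
  m <- matrix(0L, 16, 16)
  m[8, 8] <- 1L                                  # isolated pixel
  expect_equal(max(cleanupCandidates(m)), 0)

  m <- matrix(0L, 16, 16)
  m[5:9, 5:9] <- 1L; m[7, 7] <- 0L               # interior hole
  lab <- cleanupCandidates(m)
  expect_equal(max(lab), 1)
  expect_equal(sum(lab > 0), 25)                 # hole filled

  m <- matrix(0L, 16, 16)
  m[1:6, 4:9] <- 1L                              # touches row 1
  expect_equal(max(cleanupCandidates(m)), 0)
})

test_that("cleanup output never touches the image border", {
  set.seed(77)
  for (rep in 1:5) {
    m <- matrix(rbinom(400, 1, 0.4), 20, 20)
    lab <- cleanupCandidates(m)
    expect_true(all(lab[1, ] == 0) && all(lab[20, ] == 0) &&
                  all(lab[, 1] == 0) && all(lab[, 20] == 0))
    # labels consecutive 1..K
    u <- sort(unique(lab[lab > 0]))
    expect_identical(u, seq_along(u))
  }
})

test_that("H-connected bridging pixels are broken", {
  hBreak <- myelinMorph:::.hBreak
  m <- matrix(0L, 9, 9)
  m[4:6, 3] <- 1L; m[4:6, 5] <- 1L; m[5, 4] <- 1L   # H with rung at (5,4)
  out <- hBreak(m)
  expect_equal(out[5, 4], 0L)                        # rung removed
  expect_equal(sum(m) - sum(out), 1)                 # nothing else touched
  # 90-degree rotation of the pattern
  m2 <- t(m)
  out2 <- hBreak(m2)
  expect_equal(out2[4, 5], 0L)
  expect_equal(sum(m2) - sum(out2), 1)
  # a solid block contains no H configuration
  b <- matrix(0L, 9, 9); b[3:7, 3:7] <- 1L
  expect_identical(hBreak(b), b)
})
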