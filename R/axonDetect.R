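#' H-minima transform
#'
#' Suppresses all regional minima of depth less than `h`: morphological
#' reconstruction by erosion of `img + h` over `img` (8-connectivity).
#' Intensities are quantized to 256 levels before reconstruction so the
#' iteration terminates deterministically.  The output is pointwise >=
#' the input and every remaining regional minimum has depth >= h.
#'
#' @param img a [CalibratedImage-class] or numeric matrix in \[0, 1\]
#' @param h minimum depth threshold in \[0, 1\]
#' @return numeric matrix of the transformed intensities
#' @examples
#' p <- matrix(c(5, 2, 5, 1, 5) / 255, nrow = 1)
#' hMinimaTransform(p, 3 / 255) * 255   # 5 5 5 4 5
#' @export
hMinimaTransform <- function(img, h) {
  m <- .asIntensity(img)
  if (length(h) != 1 || !is.finite(h) || h < 0 || h > 1)
    stop("h must be a single value in [0, 1]")
  q <- .quantize256(m)
  hq <- as.integer(round(h * 255))
  out <- .reconstructErode(q + hq, q)
  out / 255
}

#' Extended minima
#'
#' Binary mask of the regional minima of the H-minima transform: the
#' 8-connected equal-intensity plateaus lying strictly below all their
#' outer boundary neighbors, after minima shallower than `h` have been
#' suppressed.
#'
#' @inheritParams hMinimaTransform
#' @return logical matrix marking the extended minima
#' @examples
#' p <- matrix(c(5, 2, 5, 1, 5) / 255, nrow = 1)
#' which(extendedMinima(p, 2 / 255))  # positions 2 and 4
#' which(extendedMinima(p, 3 / 255))  # position 4 only
#' @export
extendedMinima <- function(img, h) {
  hm <- .quantize256(hMinimaTransform(img, h))
  rec <- .reconstructErode(hm + 1L, hm)
  rec > hm
}

#' Axon candidate detection with two thresholds
#'
#' Pixel-wise OR of the extended-minima masks at the two depth
#' thresholds.  A lower threshold captures small axons with weak
#' axon-to-myelin contrast; a higher one captures large axons while
#' risking merges of adjacent small ones; their union keeps both.
#'
#' @param img a [CalibratedImage-class] (preprocessed so axons are dark)
#' @param params a [SegParameters-class], or a numeric length-2 vector
#'   of thresholds
#' @return logical candidate mask
#' @export
detectCandidates <- function(img, params) {
  hs <- if (is(params, "SegParameters")) params@extendedMin else as.numeric(params)
  if (length(hs) != 2) stop("two thresholds required")
  extendedMinima(img, hs[1]) | extendedMinima(img, hs[2])
}

#' Morphological cleanup of the candidate mask
#'
#' Applies, in order: (1) remove isolated foreground pixels (no
#' foreground 8-neighbor); (2) fill isolated interior background pixels
#' (all four 4-neighbors foreground); (3) morphological closing (3 x 3
#' square); (4) break H-connected configurations by deleting the center
#' pixel of an H-shaped 3 x 3 pattern (both orientations); (5)
#' morphological opening (3 x 3 square); (6) remove every connected
#' component that touches the image border.  The result is labeled
#' 8-connected with consecutive labels.
#'
#' @param mask logical or 0/1 candidate mask
#' @return integer label map (0 = background, k > 0 = object k)
#' @export
cleanupCandidates <- function(mask) {
  b <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  # (1) isolated pixels
  n8 <- .neighborSum(b, .offsets8)
  b[b == 1 & n8 == 0] <- 0L
  # (2) isolated interior holes: all 4-neighbors foreground (border
  # pixels never qualify because missing neighbors count as background)
  n4 <- .neighborSum(b, .offsets4)
  inner <- matrix(FALSE, nrow(b), ncol(b))
  inner[2:(nrow(b) - 1), 2:(ncol(b) - 1)] <- TRUE
  b[b == 0 & n4 == 4 & inner] <- 1L
  # (3) closing, 3 x 3 square
  box <- matrix(1, 3, 3)
  b <- matrix(as.integer(EBImage::closing(b, box) > 0), nrow(b), ncol(b))
  # (4) H-break: center of an H-shaped 3 x 3 configuration
  b <- .hBreak(b)
  # (5) opening, 3 x 3 square
  b <- matrix(as.integer(EBImage::opening(b, box) > 0), nrow(b), ncol(b))
  # (6) clear border-touching components, then relabel
  lab <- cpp_label(b, 8L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  if (length(border)) lab[lab %in% border] <- 0L
  relabelConsecutive(lab)
}

# delete the bridging center pixel of H-shaped 3x3 patterns:
#   1 0 1          1 1 1
#   1 1 1   and    0 1 0
#   1 0 1          1 1 1
.hBreak <- function(b) {
  fg <- function(dr, dc) .shiftMatrix(b, dr, dc, fill = 0L)
  nw <- fg(1, 1);  n <- fg(1, 0);  ne <- fg(1, -1)
  w  <- fg(0, 1);                  e  <- fg(0, -1)
  sw <- fg(-1, 1); s <- fg(-1, 0); se <- fg(-1, -1)
  h1 <- nw & sw & ne & se & w & e & !n & !s   # vertical bars, horizontal rung
  h2 <- nw & sw & ne & se & n & s & !w & !e   # horizontal bars, vertical rung
  b[b == 1 & (h1 | h2)] <- 0L
  b
}

#' Relabel a label map to consecutive labels 1..K
#'
#' @param lab integer label map
#' @return integer label map with labels renumbered consecutively in
#'   ascending order of the original labels
#' @export
relabelConsecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (length(u) == 0 || identical(u, seq_along(u))) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  out <- match(lab, u, nomatch = 0L)
  dim(out) <- dim(lab)
  storage.mode(out) <- "integer"
  out
}

#' Label a binary mask
#'
#' 8-connected (default) component labeling with consecutive labels in
#' raster-scan discovery order.
#'
#' @param mask logical or 0/1 matrix
#' @param connectivity 4 or 8
#' @return integer label map
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  b <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  cpp_label(b, as.integer(connectivity))
}
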