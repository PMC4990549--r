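# fixtures built in code

# a single clean annulus on background, centered; radii in um
annulusImage <- function(size = 128, px = 0.1, cx = (size + 1) / 2,
                         cy = (size + 1) / 2, rIn = 2, rOut = 3,
                         iAxon = 0.1, iBg = 0.45, iMy = 0.85,
                         blur = 0) {
  m <- matrix(iBg, size, size)
  dy <- (rep(seq_len(size), times = size) - cy) * px
  dx <- (rep(seq_len(size), each = size) - cx) * px
  r <- sqrt(dx^2 + dy^2)
  m[r <= rOut] <- iMy
  m[r <= rIn] <- iAxon
  if (blur > 0) m <- pmin(pmax(EBImage::gblur(m, blur), 0), 1)
  CalibratedImage(m, px)
}

# disk mask as a matrix (for feature tests)
diskMask <- function(size, r, cx = (size + 1) / 2, cy = (size + 1) / 2) {
  dy <- rep(seq_len(size), times = size) - cy
  dx <- rep(seq_len(size), each = size) - cx
  matrix(sqrt(dx^2 + dy^2) <= r, size, size)
}

# a synthetic "myelinRing" built directly from pixel-index masks
ringFromMasks <- function(axonIdx, myelinIdx, centroid = c(0, 0)) {
  list(centroid = centroid, axonPixels = axonIdx, myelinPixels = myelinIdx,
       failure = NULL)
}

# small OM-like phantom used across tests (noise off for determinism
# of the geometry checks)
smallPhantom <- function(seed = 3, nFibers = 8, noise = 0) {
  generatePhantom(phantomPreset("OM", imageSize = 256L,
                                nFibers = as.integer(nFibers),
                                nDistractors = 2L, noiseSigma = noise,
                                seed = as.integer(seed)))
}
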