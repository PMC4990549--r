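# internal helpers shared across modules

# accept a CalibratedImage or a bare matrix wherever only intensities matter
.asIntensity <- function(img) {
  if (is(img, "CalibratedImage")) return(img@intensities)
  if (is.matrix(img) && is.numeric(img)) return(img)
  stop("expected a CalibratedImage or a numeric matrix")
}

# quantize [0,1] intensities to 256 integer levels so that iterative
# morphological reconstruction terminates deterministically
.quantize256 <- function(m) {
  q <- as.integer(round(m * 255))
  dim(q) <- dim(m)
  q
}

# grayscale reconstruction by erosion (8-connectivity) via the dual
# dilation reconstruction on inverted integer images; marker >= mask
.reconstructErode <- function(marker, mask) {
  top <- max(marker, mask)
  top - cpp_reconstruct_dilate(top - marker, top - mask)
}

# shift a matrix by (dr, dc), padding with `fill`
.shiftMatrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# count of foreground neighbors for each pixel under the given offsets
.neighborSum <- function(bin, offsets) {
  acc <- matrix(0, nrow(bin), ncol(bin))
  for (k in seq_len(nrow(offsets)))
    acc <- acc + .shiftMatrix(bin, offsets[k, 1], offsets[k, 2], fill = 0)
  acc
}

.offsets8 <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
.offsets8 <- .offsets8[!(.offsets8[, 1] == 0 & .offsets8[, 2] == 0), ]
.offsets4 <- matrix(c(-1, 0, 1, 0, 0, -1, 0, 1), ncol = 2, byrow = TRUE)

# standard deviation that is 0 (not NA) for a single observation
.sd0 <- function(x) if (length(x) < 2) 0 else sd(x)

# bilinear interpolation of matrix m at fractional (row, col) positions;
# positions outside the grid are clamped to the nearest pixel
.bilinear <- function(m, r, c) {
  r <- as.vector(r); c <- as.vector(c)
  nr <- nrow(m); nc <- ncol(m)
  clamped <- r < 1 | r > nr | c < 1 | c > nc
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  v <- m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
  attr(v, "clamped") <- any(clamped)
  v
}

# circular moving average of period-n sequence x with odd window w
.circularSmooth <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  h <- (w - 1) %/% 2
  idx <- outer(seq_len(n), -h:h, `+`)
  idx <- ((idx - 1) %% n) + 1
  rowMeans(matrix(x[idx], nrow = n))
}

# pixels of each labeled object as (row, col) matrices, one pass
.objectPixelList <- function(labels) {
  idx <- which(labels > 0)
  if (length(idx) == 0) return(list())
  nr <- nrow(labels)
  sp <- split(idx, labels[idx])
  lapply(sp, function(i)
    cbind(row = ((i - 1) %% nr) + 1, col = ((i - 1) %/% nr) + 1))
}

# shoelace area of a closed polygon given vertex coordinates
.polyArea <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
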