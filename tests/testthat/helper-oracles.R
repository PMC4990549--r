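# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# morphological reconstruction by erosion: iterate
#   R <- pmax(mask, erode8(R))  from R = marker (>= mask)  until stable
oracle_reconstruct_erode <- function(marker, mask) {
  stopifnot(all(marker >= mask))
  R <- marker
  nr <- nrow(R); nc <- ncol(R)
  repeat {
    E <- R
    for (r in seq_len(nr)) {
      for (c in seq_len(nc)) {
        rs <- max(1, r - 1):min(nr, r + 1)
        cs <- max(1, c - 1):min(nc, c + 1)
        E[r, c] <- min(R[rs, cs])
      }
    }
    Rn <- pmax(mask, E)
    if (all(Rn == R)) return(R)
    R <- Rn
  }
}

# regional minima by plateau flood fill: an 8-connected equal-value
# plateau is a minimum iff no neighbor of any plateau pixel is lower
oracle_regional_minima <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(FALSE, nr, nc)
  visited <- matrix(FALSE, nr, nc)
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (visited[r0, c0]) next
      v <- img[r0, c0]
      stack <- list(c(r0, c0)); visited[r0, c0] <- TRUE
      plateau <- list(); isMin <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        plateau[[length(plateau) + 1]] <- p
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          if (img[rr, cc] == v) {
            if (!visited[rr, cc]) {
              visited[rr, cc] <- TRUE
              stack[[length(stack) + 1]] <- c(rr, cc)
            }
          } else if (img[rr, cc] < v) isMin <- FALSE
        }
      }
      if (isMin)
        for (p in plateau) out[p[1], p[2]] <- TRUE
    }
  }
  out
}

# extended minima = regional minima of the reconstruction-by-erosion
# of (img + h) over img, all in integer arithmetic
oracle_extended_minima <- function(imgInt, hInt) {
  rec <- oracle_reconstruct_erode(imgInt + hInt, imgInt)
  oracle_regional_minima(rec)
}

# exhaustive enumeration of circularly-closed paths on a polar grid
oracle_circular_path <- function(grid, maxStep, maximize = FALSE) {
  R <- nrow(grid); A <- ncol(grid)
  paths <- as.matrix(expand.grid(rep(list(seq_len(R)), A)))
  best <- if (maximize) -Inf else Inf
  bp <- NULL
  for (i in seq_len(nrow(paths))) {
    p <- paths[i, ]
    if (any(abs(diff(c(p, p[1]))) > maxStep)) next
    cost <- sum(grid[cbind(p, seq_len(A))])
    better <- if (maximize) cost > best else cost < best
    if (better) { best <- cost; bp <- p }
  }
  list(cost = best, path = bp)
}

# brute-force centroid matching: every test object whose rounded
# centroid lies in a ref object is a TP candidate; each ref keeps the
# closest candidate
oracle_match <- function(test, ref) {
  cent <- function(lab) {
    ids <- sort(unique(lab[lab > 0]))
    t(vapply(ids, function(k) {
      px <- which(lab == k, arr.ind = TRUE)
      c(k, mean(px[, 2]), mean(px[, 1]))
    }, numeric(3)))
  }
  tc <- cent(test); rc <- cent(ref)
  nT <- if (length(tc)) nrow(tc) else 0
  nR <- if (length(rc)) nrow(rc) else 0
  taken <- c(); pairs <- NULL
  for (j in seq_len(nR)) {
    bestD <- Inf; bestI <- NA
    for (i in seq_len(nT)) {
      if (tc[i, 1] %in% taken) next
      hit <- ref[round(tc[i, 3]), round(tc[i, 2])]
      if (hit != rc[j, 1]) next
      d <- sqrt((tc[i, 2] - rc[j, 2])^2 + (tc[i, 3] - rc[j, 3])^2)
      if (d < bestD) { bestD <- d; bestI <- i }
    }
    if (!is.na(bestI)) {
      taken <- c(taken, tc[bestI, 1])
      pairs <- rbind(pairs, c(tc[bestI, 1], rc[j, 1]))
    }
  }
  TP <- length(taken)
  list(TP = TP, FP = nT - TP, FN = nR - TP, pairs = pairs)
}
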