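#' Build the per-fiber record list from cleaned myelin rings
#'
#' One record per surviving ring.  Diameters are equivalent-circle
#' diameters of the axon mask and of the fiber (axon plus myelin) mask;
#' g-ratio is their ratio (area-based, stable for non-circular fibers);
#' myelin thickness is half the diameter difference.  Ids are
#' consecutive from 1.
#'
#' @param rings list of successful rings from [segmentMyelin] /
#'   [conflictClean]
#' @param pixelSize micrometers per pixel
#' @param imageDim image dimensions (rows, cols)
#' @return an [AxonList-class]
#' @export
buildAxonList <- function(rings, pixelSize, imageDim) {
  rings <- Filter(function(r) is.null(r$failure), rings)
  n <- length(rings)
  imageDim <- as.integer(imageDim)
  if (n == 0) {
    rec <- data.frame(axonId = integer(), x = numeric(), y = numeric(),
                      axonAreaPx = numeric(), axonAreaUm2 = numeric(),
                      myelinAreaPx = numeric(), myelinAreaUm2 = numeric(),
                      axonEquivDiameter = numeric(),
                      fiberEquivDiameter = numeric(),
                      gRatio = numeric(), myelinThickness = numeric())
    return(new("AxonList", records = rec, axonMasks = list(),
               myelinMasks = list(), pixelSize = pixelSize,
               imageDim = imageDim))
  }
  nr <- imageDim[1]
  rec <- lapply(seq_len(n), function(i) {
    r <- rings[[i]]
    aPx <- length(r$axonPixels); mPx <- length(r$myelinPixels)
    rows <- ((r$axonPixels - 1) %% nr) + 1
    cols <- ((r$axonPixels - 1) %/% nr) + 1
    dAx <- pixelSize * sqrt(4 * aPx / pi)
    dFib <- pixelSize * sqrt(4 * (aPx + mPx) / pi)
    data.frame(axonId = i, x = mean(cols), y = mean(rows),
               axonAreaPx = aPx, axonAreaUm2 = aPx * pixelSize^2,
               myelinAreaPx = mPx, myelinAreaUm2 = mPx * pixelSize^2,
               axonEquivDiameter = dAx, fiberEquivDiameter = dFib,
               gRatio = dAx / dFib, myelinThickness = (dFib - dAx) / 2)
  })
  new("AxonList", records = do.call(rbind, rec),
      axonMasks = lapply(rings, `[[`, "axonPixels"),
      myelinMasks = lapply(rings, `[[`, "myelinPixels"),
      pixelSize = pixelSize, imageDim = imageDim)
}

#' Export fiber records as CSV
#'
#' One row per fiber, columns in record order (pixel masks excluded),
#' micrometer units, 4 decimal places, ordered by axonId.  A read-back
#' of the file reproduces all numeric fields exactly at the written
#' precision.
#'
#' @param axl an [AxonList-class]
#' @param path output path
#' @return invisibly, the path
#' @export
exportAxonCsv <- function(axl, path) {
  r <- axonRecords(axl)
  r <- r[order(r$axonId), , drop = FALSE]
  num <- vapply(r, is.numeric, TRUE)
  r[num] <- lapply(r[num], function(v) round(v, 4))
  write.csv(r, path, row.names = FALSE)
  invisible(path)
}

#' Render a metric-valued label image
#'
#' Background 0; the pixels of each fiber (axon or myelin mask) carry
#' the fiber's metric value.  Overlapping pixels resolve to the higher
#' axonId.
#'
#' @param axl an [AxonList-class]
#' @param metric one of "id", "axonEquivDiameter", "gRatio",
#'   "myelinThickness"
#' @param display "axon" or "myelin"
#' @return numeric matrix (integer for metric = "id")
#' @export
renderLabelMap <- function(axl, metric = c("id", "axonEquivDiameter",
                                           "gRatio", "myelinThickness"),
                           display = c("axon", "myelin")) {
  metric <- match.arg(metric)
  display <- match.arg(display)
  rec <- axonRecords(axl)
  out <- matrix(if (metric == "id") 0L else 0, axl@imageDim[1],
                axl@imageDim[2])
  masks <- if (display == "axon") axonMasks(axl) else myelinMasks(axl)
  for (i in order(rec$axonId)) {
    v <- switch(metric, id = rec$axonId[i],
                axonEquivDiameter = rec$axonEquivDiameter[i],
                gRatio = rec$gRatio[i],
                myelinThickness = rec$myelinThickness[i])
    out[masks[[i]]] <- v
  }
  out
}
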