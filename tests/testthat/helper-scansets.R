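# Fixtures built in code: a uniform piecewise-constant scan set for
# arithmetic checks, and a cached full-size phantom shared by the
# integration tests (generated once per test run).

# layer heights in rows (integer), one value per layer; levels are
# per-layer constant reflectivities in device units
uniformScanSet <- function(nRows = 140L, nCols = 49L, dy = 2,
                           lateralExtentMm = 6,
                           heightsRows = c("RNFL" = 10, "GCL+IPL" = 15,
                                           "INL" = 8, "OPL" = 8,
                                           "ONL+IS" = 45, "OS" = 14,
                                           "RPE" = 10),
                           levels = c("RNFL" = 900, "GCL+IPL" = 500,
                                      "INL" = 300, "OPL" = 450,
                                      "ONL+IS" = 250, "OS" = 700,
                                      "RPE" = 1000),
                           ilmRow = 10, vitreous = 10, choroid = 200,
                           signalStrength = 9L,
                           perScanHeights = NULL,   # list of 6 height vectors
                           shadowCols = integer(), shadowFactor = 1) {
  mkScan <- function(h, angle) {
    b <- c(ilmRow, ilmRow + cumsum(h[retinalLayers()]))
    B <- matrix(rep(b, nCols), nrow = 8L,
                dimnames = list(boundaryNames(), NULL))
    img <- matrix(vitreous, nRows, nCols)
    for (j in 1:7) {
      rows <- seq.int(b[j] + 1L, b[j + 1L])
      img[rows, ] <- levels[[retinalLayers()[j]]]
    }
    if (b[8L] + 1L <= nRows) img[seq.int(b[8L] + 1L, nRows), ] <- choroid
    if (length(shadowCols))
      img[seq.int(b[1L] + 1L, nRows), shadowCols] <-
        img[seq.int(b[1L] + 1L, nRows), shadowCols] * shadowFactor
    list(scan = BScan(img, axialSpacingUm = dy,
                      lateralExtentMm = lateralExtentMm,
                      foveaColumn = (nCols + 1L) %/% 2L,
                      scanAngleDeg = angle, signalStrength = signalStrength,
                      eyeId = "uniform", subjectId = "u_subj",
                      groupLabel = "H"),
         seg = LayerSegmentation(B))
  }
  hh <- if (is.null(perScanHeights)) replicate(6, heightsRows,
                                               simplify = FALSE)
        else perScanHeights
  made <- lapply(1:6, function(i) mkScan(hh[[i]], (i - 1) * 30))
  RadialScanSet(lapply(made, `[[`, "scan"), lapply(made, `[[`, "seg"))
}

# one ROI covering a full rectangular block of a matrix (for direct
# metric arithmetic)
blockROI <- function(rows, cols, layerName = "RNFL",
                     region = "across_all") {
  n <- length(cols)
  new("LayerROI", layerName = layerName, region = region,
      columns = as.integer(cols),
      top = rep(min(rows) - 1, n), bottom = rep(max(rows), n),
      rowFirst = rep(as.integer(min(rows)), n),
      rowLast = rep(as.integer(max(rows)), n), scanIndex = 0L)
}

# wrap a bare matrix as a BScan with default calibration
matScan <- function(m, dy = 2, lateralExtentMm = 6) {
  BScan(m, axialSpacingUm = dy, lateralExtentMm = lateralExtentMm,
        foveaColumn = max(1L, ncol(m) %/% 2L))
}

# cached full-size phantom: generated once, preprocessed once
.fixtures <- new.env(parent = emptyenv())

cachedPhantom <- function() {
  if (is.null(.fixtures$phantom))
    .fixtures$phantom <- generatePhantomEye(phantomSpec(seed = 2024L))
  .fixtures$phantom
}

cachedPreprocessed <- function() {
  if (is.null(.fixtures$pp))
    .fixtures$pp <- preprocessScanSet(cachedPhantom()$scanSet)
  .fixtures$pp
}

cachedFeatures <- function() {
  if (is.null(.fixtures$features))
    .fixtures$features <- extractFeatures(cachedPreprocessed(),
                                          preprocessed = TRUE)
  .fixtures$features
}

# small phantom for I/O and invariance tests
smallPhantomSpec <- function(seed = 5L, ...) {
  phantomSpec(nColumns = 96L, nRows = 320L, ilmOffsetRows = 40,
              shadowColumns = c(30:32), seed = seed, ...)
}

# brute-force GLCM contrast by pair enumeration (independent oracle)
bruteContrast <- function(lv, offsets) {
  sumsq <- 0; npairs <- 0
  n <- nrow(lv); m <- ncol(lv)
  for (off in offsets) {
    for (r in seq_len(n)) for (k in seq_len(m)) {
      r2 <- r + off[1]; k2 <- k + off[2]
      if (r2 >= 1 && r2 <= n && k2 >= 1 && k2 <= m &&
          !is.na(lv[r, k]) && !is.na(lv[r2, k2])) {
        sumsq <- sumsq + (lv[r, k] - lv[r2, k2])^2
        npairs <- npairs + 1
      }
    }
  }
  sumsq / npairs
}

# quantization identical to the implementation's contract: equal-width
# bins over [0, q99 of the scan], top bin absorbs the overflow
quantizeLevels <- function(vals, nLevels, hi)
  pmin(pmax(floor(vals / hi * nLevels), 0), nLevels - 1)
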