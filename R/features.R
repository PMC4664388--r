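## The five per-ROI metrics. Each returns a list(value, n) where n is
## the number of columns that contributed; an undefined metric is
## NA_real_, never 0 (0 is a valid contrast value).

.METRICS <- c("thickness_um", "contrast_au", "fractal_dimension_au",
              "layer_index_au", "total_reflectance_db")

#' Metric names produced by the feature extractor
#'
#' @return Character vector: `thickness_um`, `contrast_au`,
#'   `fractal_dimension_au`, `layer_index_au`, `total_reflectance_db`.
#' @export
metricNames <- function() .METRICS

#' Mean layer thickness
#'
#' Mean over the ROI's columns of the fractional boundary distance
#' `bottom - top`, converted to micrometres by the axial pixel spacing.
#'
#' @param roi A [LayerROI-class].
#' @param axialSpacingUm Micrometres per row.
#' @return List with `value` (um, `NA` for an empty ROI) and `n`
#'   (columns used).
#' @export
layerThickness <- function(roi, axialSpacingUm) {
  if (!length(roi@columns)) return(list(value = NA_real_, n = 0L))
  list(value = mean(roi@bottom - roi@top) * axialSpacingUm,
       n = length(roi@columns))
}

## quantize values to 0 .. nLevels-1 over the fixed range [0, hi]
.quantize <- function(values, nLevels, hi) {
  if (hi <= 0) return(rep(NA_integer_, length(values)))
  lv <- floor(values / hi * nLevels)
  pmin(pmax(lv, 0L), nLevels - 1L)
}

#' GLCM contrast of a layer region
#'
#' Second-order statistical texture: the ROI's (normalized)
#' reflectivities are quantized to `nLevels` equal-width bins over the
#' fixed range from 0 to the 99th percentile of the whole scan (values
#' above it land in the top bin); a symmetric gray-level co-occurrence
#' matrix is accumulated over the given pixel offsets, counting only
#' pairs with both pixels inside the ROI; contrast is
#' `sum (i - j)^2 p(i, j)`.
#'
#' Quantizing against a scan-relative range makes the statistic
#' invariant to global gain.
#'
#' @param roi A [LayerROI-class].
#' @param scan The source [BScan-class] (provides the pixel values and
#'   the quantization range).
#' @param nLevels Number of gray levels (default 64).
#' @param offsets List of `c(dr, dc)` pixel offsets, pooled
#'   symmetrically (default axial and lateral nearest neighbours).
#' @param quantileRange Upper quantile of the scan fixing the
#'   quantization range (default 0.99).
#' @return List with `value` (a.u., `NA` if no co-occurring pair
#'   exists) and `n` (columns in the ROI).
#' @export
glcmContrast <- function(roi, scan, nLevels = 64L,
                         offsets = list(c(0L, 1L), c(1L, 0L)),
                         quantileRange = 0.99) {
  if (!length(roi@columns)) return(list(value = NA_real_, n = 0L))
  r <- scan@reflectivity
  hi <- quantile(r, quantileRange, names = FALSE)
  lv <- matrix(NA_real_, nrow(r), ncol(r))
  for (i in seq_along(roi@columns)) {
    rows <- roi@rowFirst[i]:roi@rowLast[i]
    k <- roi@columns[i]
    lv[rows, k] <- .quantize(r[rows, k], as.integer(nLevels), hi)
  }
  sumsq <- 0; npairs <- 0
  n <- nrow(lv); m <- ncol(lv)
  for (off in offsets) {
    dr <- off[1L]; dc <- off[2L]
    if (dr >= n || dc >= m) next
    a <- lv[seq_len(n - dr), seq_len(m - dc), drop = FALSE]
    b <- lv[seq_len(n - dr) + dr, seq_len(m - dc) + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    sumsq <- sumsq + sum((a[ok] - b[ok])^2)
    npairs <- npairs + sum(ok)
  }
  if (npairs == 0L) return(list(value = NA_real_, n = length(roi@columns)))
  ## the symmetric GLCM counts each pair in both orders; contrast is the
  ## same either way, so the one-directional mean suffices
  list(value = sumsq / npairs, n = length(roi@columns))
}

## least-squares slope of y on x without lm() overhead
.slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

#' Power-spectrum fractal dimension of one axial profile
#'
#' Mean-detrends the profile, computes the discrete Fourier power
#' spectrum and fits `ln P(omega) ~ -beta ln omega` by least squares
#' over the positive frequencies up to the Nyquist frequency (the zero
#' frequency is removed by the detrend). The fractal dimension of the
#' profile is `FD = (5 - beta) / 2`.
#'
#' @param profile Numeric vector (one A-scan's reflectance within a
#'   layer).
#' @param minLen Minimum profile length (default 8 samples).
#' @return The FD estimate, or `NA` when the profile is too short, has
#'   zero variance, or fewer than two usable spectrum points.
#' @export
profileFractalDimension <- function(profile, minLen = 8L) {
  nlen <- length(profile)
  if (nlen < minLen) return(NA_real_)
  x <- profile - mean(profile)
  if (all(x == 0)) return(NA_real_)
  P <- Mod(fft(x))^2
  m <- seq_len(nlen %/% 2L)       # positive frequencies up to Nyquist
  P <- P[m + 1L]
  keep <- P > 0
  if (sum(keep) < 2L) return(NA_real_)
  beta <- -.slope(log(m[keep]), log(P[keep]))
  (5 - beta) / 2
}

#' Fractal dimension of a layer region
#'
#' Applies [profileFractalDimension()] to the axial reflectance profile
#' of every included column and averages the admissible estimates
#' (unweighted).
#'
#' @param roi A [LayerROI-class].
#' @param scan The source [BScan-class].
#' @param minLen Minimum per-column profile length in samples.
#' @return List with `value` (a.u., `NA` when no column is admissible)
#'   and `n` (columns that produced an estimate).
#' @export
fractalDimension <- function(roi, scan, minLen = 8L) {
  if (!length(roi@columns)) return(list(value = NA_real_, n = 0L))
  fds <- vapply(.roiProfiles(roi, scan@reflectivity),
                profileFractalDimension, 0, minLen = minLen)
  fds <- fds[!is.na(fds)]
  if (!length(fds)) return(list(value = NA_real_, n = 0L))
  list(value = mean(fds), n = length(fds))
}

#' Total reflectance of a layer region, in decibels
#'
#' Per column `k`, the total reflectance is the sum of the (normalized)
#' reflectivity values in the layer interval — equivalently the mean
#' reflectance times the local thickness in pixels. The region value is
#' `10 log10` of the mean of the per-column totals (linear-domain
#' averaging, then dB conversion).
#'
#' @param roi A [LayerROI-class].
#' @param scan The source [BScan-class] (should be NRPE-normalized).
#' @return List with `value` (dB; `NA` for an empty ROI or non-positive
#'   mean total) and `n` (columns used).
#' @export
totalReflectance <- function(roi, scan) {
  if (!length(roi@columns)) return(list(value = NA_real_, n = 0L))
  tr <- vapply(.roiProfiles(roi, scan@reflectivity), sum, 0)
  m <- mean(tr)
  if (m <= 0) return(list(value = NA_real_, n = length(roi@columns)))
  list(value = 10 * log10(m), n = length(roi@columns))
}

#' Layer index of a layer region
#'
#' Per column `k`, `LI_k = MR_k * H_k / I_sa` with the local thickness
#' `H_k` in pixels, which reduces to the column's reflectivity sum
#' divided by `I_sa`, the 99th-percentile reflectivity of the whole
#' scan image. The region value is the unweighted mean of `LI_k` over
#' included columns. Because `I_sa` scales with the image, the index is
#' invariant to global gain.
#'
#' @param roi A [LayerROI-class].
#' @param scan The source [BScan-class].
#' @param saturationQuantile Quantile of the scan defining `I_sa`
#'   (default 0.99).
#' @return List with `value` (a.u.) and `n` (columns used).
#' @export
layerIndex <- function(roi, scan, saturationQuantile = 0.99) {
  if (!length(roi@columns)) return(list(value = NA_real_, n = 0L))
  isa <- quantile(scan@reflectivity, saturationQuantile, names = FALSE)
  if (isa == 0) stop("saturation reflectivity I_sa is zero")
  li <- vapply(.roiProfiles(roi, scan@reflectivity), sum, 0) / isa
  list(value = mean(li), n = length(roi@columns))
}

## regions at which a layer is reported (inner layers skip the foveolar
## disc); across_all is always included
.layerRegions <- function(layerName) {
  zones <- if (layerName %in% .OUTER_LAYERS) .REGION_RADII$region
           else setdiff(.REGION_RADII$region, "foveolar")
  c(zones, "across_all")
}

#' Extract the full feature table of one eye
#'
#' For every permitted layer x region combination (the inner layers —
#' RNFL, GCL+IPL, GCC, INL, OPL — are not measured in the foveolar
#' disc) each metric is computed per scan and averaged over the six
#' radial scans into one row per (eye, layer, region, metric).
#' Thickness uses all region columns; the reflectance-based metrics
#' (contrast, fractal dimension, layer index, total reflectance)
#' exclude vessel-shadow columns. GCC metrics are computed on the
#' composite ILM-to-GCL+IPL/INL interval, not by summing the sub-layer
#' values (for thickness the two agree).
#'
#' @param scanSet A [RadialScanSet-class]. Unless `preprocessed = TRUE`
#'   it is first passed through [preprocessScanSet()].
#' @param preprocessed Set to `TRUE` when the set has already been
#'   denoised/normalized and its shadow columns filled.
#' @param denoise,iterations,thresholdFactor Passed to
#'   [preprocessScanSet()] when preprocessing runs.
#' @param nLevels,offsets GLCM parameters, see [glcmContrast()].
#' @param minLen Minimum profile length for the fractal dimension.
#' @return A long data.frame with columns
#'   `eye, subject, group, layer, region, metric, value`; undefined
#'   metrics are `NA`.
#' @export
extractFeatures <- function(scanSet, preprocessed = FALSE, denoise = TRUE,
                            iterations = 10L, thresholdFactor = 0.75,
                            nLevels = 64L,
                            offsets = list(c(0L, 1L), c(1L, 0L)),
                            minLen = 8L) {
  if (!preprocessed)
    scanSet <- preprocessScanSet(scanSet, denoise = denoise,
                                 iterations = iterations,
                                 thresholdFactor = thresholdFactor)
  dy <- axialSpacingUm(scanSet)
  rows <- list()
  for (layer in analysisLayers()) {
    for (region in .layerRegions(layer)) {
      perScan <- matrix(NA_real_, 6L, length(.METRICS),
                        dimnames = list(NULL, .METRICS))
      for (i in seq_len(6L)) {
        scan <- scanSet@scans[[i]]
        seg <- scanSet@segmentations[[i]]
        shadows <- scanSet@shadowColumns[[i]]
        roiAll <- buildLayerROI(scan, seg, layer, region, scanIndex = i)
        roiClean <- buildLayerROI(scan, seg, layer, region,
                                  excludedColumns = shadows, scanIndex = i)
        perScan[i, "thickness_um"] <- layerThickness(roiAll, dy)$value
        perScan[i, "contrast_au"] <-
          glcmContrast(roiClean, scan, nLevels = nLevels,
                       offsets = offsets)$value
        perScan[i, "fractal_dimension_au"] <-
          fractalDimension(roiClean, scan, minLen = minLen)$value
        perScan[i, "layer_index_au"] <- layerIndex(roiClean, scan)$value
        perScan[i, "total_reflectance_db"] <-
          totalReflectance(roiClean, scan)$value
      }
      vals <- colMeans(perScan, na.rm = TRUE)
      vals[is.nan(vals)] <- NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        eye = eyeId(scanSet), subject = subjectId(scanSet),
        group = groupLabel(scanSet), layer = layer, region = region,
        metric = .METRICS, value = unname(vals),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
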