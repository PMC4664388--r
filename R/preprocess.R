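#' Complex diffusion speckle denoising
#'
#' Nonlinear complex diffusion for speckle reduction. The image is
#' embedded in the complex plane and evolved under
#' `dI/dt = div(c grad I)` with the complex conductance
#' `c = exp(i theta) / (1 + (Im(I) / (k theta))^2)`: for small times the
#' imaginary part approximates a smoothed Laplacian (an edge detector),
#' so diffusion is damped across edges while smooth regions are
#' averaged. The divergence form with half-point conductances conserves
#' the image mean exactly; the real part is returned.
#'
#' @param reflectivity Non-negative numeric matrix.
#' @param iterations Number of explicit time steps (default 10; 0
#'   returns the input unchanged).
#' @param timeStep Explicit step size (default 0.2; stability requires
#'   `timeStep <= 0.25` for the 4-neighbour stencil).
#' @param edgeThreshold Edge scale as a fraction of the image maximum
#'   (default 0.1); gradients whose evolving imaginary part exceeds
#'   `edgeThreshold * max(reflectivity) * theta` diffuse little.
#' @param theta Phase angle of the diffusion coefficient (radians).
#' @return Denoised matrix of the same shape, real part only.
#' @export
denoiseComplexDiffusion <- function(reflectivity, iterations = 10L,
                                    timeStep = 0.2, edgeThreshold = 0.1,
                                    theta = pi / 30) {
  if (any(!is.finite(reflectivity)))
    stop("reflectivity has non-finite values")
  stopifnot(timeStep > 0, edgeThreshold > 0, theta > 0)
  iterations <- as.integer(iterations)
  if (iterations == 0L) return(reflectivity)
  k <- edgeThreshold * max(reflectivity)
  if (k == 0) return(reflectivity)   # all-zero image: nothing to diffuse
  I <- reflectivity * (1 + 0i)
  n <- nrow(I); m <- ncol(I)
  eitheta <- exp(1i * theta)
  for (it in seq_len(iterations)) {
    cc <- eitheta / (1 + (Im(I) / (k * theta))^2)
    ## neighbour differences with replicated (Neumann) boundaries
    dN <- rbind(0, I[-n, ] - I[-1, ])          # I[r-1] - I[r]
    dS <- rbind(I[-1, ] - I[-n, ], 0)          # I[r+1] - I[r]
    dW <- cbind(0, I[, -m] - I[, -1])
    dE <- cbind(I[, -1] - I[, -m], 0)
    cN <- rbind(cc[1, ], (cc[-n, ] + cc[-1, ]) / 2)
    cS <- rbind((cc[-1, ] + cc[-n, ]) / 2, cc[n, ])
    cW <- cbind(cc[, 1], (cc[, -m] + cc[, -1]) / 2)
    cE <- cbind((cc[, -1] + cc[, -m]) / 2, cc[, m])
    I <- I + timeStep * (cN * dN + cS * dS + cW * dW + cE * dE)
  }
  Re(I)
}

#' Locate retinal vessel shadows from a shadowgram
#'
#' Inner retinal vessels cast axial shadows that attenuate everything
#' beneath them. The shadowgram `s(k)` is the mean reflectivity of
#' column `k` over the outer retinal band (ONL+IS through RPE); a
#' column is flagged when `s(k) < thresholdFactor * median(s)`, and
#' each contiguous run of flagged columns is dilated by one column on
#' either side to catch the shadow penumbra.
#'
#' @param scan A [BScan-class].
#' @param segmentation Matching [LayerSegmentation-class].
#' @param thresholdFactor Fraction of the median shadowgram value below
#'   which a column is flagged (default 0.75).
#' @return Sorted integer vector of flagged columns (possibly empty).
#' @export
detectVesselShadows <- function(scan, segmentation, thresholdFactor = 0.75) {
  r <- scan@reflectivity
  b <- segmentation@boundaries
  nc <- ncol(r)
  s <- rep(NA_real_, nc)
  px <- .pixelRows(b["OPL/ONL+IS", ], b["RPE/choroid", ])
  for (k in seq_len(nc)) {
    if (px$last[k] >= px$first[k])
      s[k] <- mean(r[px$first[k]:px$last[k], k])
  }
  usable <- which(!is.na(s))
  if (!length(usable)) {
    warning("shadowgram band empty at every column; no shadows detected")
    return(integer())
  }
  med <- median(s[usable])
  if (med <= 0) {
    warning("shadowgram has no signal; no shadows detected")
    return(integer())
  }
  flagged <- usable[s[usable] < thresholdFactor * med]
  if (!length(flagged)) return(integer())
  ## dilate each contiguous run by one column on each side
  runs <- split(flagged, cumsum(c(1L, diff(flagged) != 1L)))
  out <- unlist(lapply(runs, function(run) {
    (min(run) - 1L):(max(run) + 1L)
  }))
  sort(unique(out[out >= 1L & out <= nc]))
}

#' Normalize a scan to its RPE reflectance (NRPE)
#'
#' Divides every pixel by the mean reflectivity of the RPE layer of the
#' same scan, computed over non-shadow columns, so that the RPE band of
#' the output has mean 1. Factors extrinsic to the retina (focus,
#' media opacity, device gain) scale the whole image and therefore
#' cancel; the operation is idempotent.
#'
#' @param scan A [BScan-class].
#' @param segmentation Matching [LayerSegmentation-class].
#' @param excludedColumns Columns to exclude from the reference mean
#'   (vessel shadows).
#' @return The scan with normalized reflectivity.
#' @export
normalizeToRPE <- function(scan, segmentation, excludedColumns = integer()) {
  r <- scan@reflectivity
  b <- segmentation@boundaries
  cols <- setdiff(seq_len(ncol(r)), as.integer(excludedColumns))
  px <- .pixelRows(b["OS/RPE", ], b["RPE/choroid", ])
  vals <- unlist(lapply(cols, function(k) {
    if (px$last[k] >= px$first[k]) r[px$first[k]:px$last[k], k] else numeric()
  }))
  if (!length(vals) || mean(vals) == 0)
    stop("no reference signal: RPE band mean is zero or empty")
  scan@reflectivity <- r / mean(vals)
  scan
}

#' Center-point-thickness scan quality factor (SQF)
#'
#' The center point thickness (CPT) of each radial scan is the total
#' retinal thickness (ILM to the inner boundary of the OS/RPE junction)
#' at the foveal center column. The quality factor is 1 when the
#' percent sample standard deviation of the six CPTs is at most 10%;
#' larger variability indicates patient movement or boundary error.
#'
#' @param scanSet A [RadialScanSet-class].
#' @return A [QualityReport-class].
#' @export
computeSQF <- function(scanSet) {
  cpt <- vapply(seq_len(6L), function(i) {
    scan <- scanSet@scans[[i]]
    b <- scanSet@segmentations[[i]]@boundaries
    k <- scan@foveaColumn
    (b["OS/RPE", k] - b["ILM", k]) * scan@axialSpacingUm
  }, 0)
  m <- mean(cpt)
  if (m == 0) stop("center point thickness mean is zero")
  sdPct <- 100 * sd(cpt) / m
  new("QualityReport",
      cptValuesUm = unname(cpt),
      cptSdPercent = sdPct,
      sqf = if (sdPct <= 10) 1L else 0L,
      minSignalStrength = min(vapply(scanSet@scans,
                                     function(s) s@signalStrength, 0L)))
}

#' Accept or reject a scan set on quality grounds
#'
#' A set is accepted only when its scan quality factor is 1 (CPT
#' percent SD at most 10%) and every scan's signal strength is above
#' `minSignal` (default 6, i.e. SS >= 7 required).
#'
#' @param scanSet A [RadialScanSet-class].
#' @param report A [QualityReport-class], typically from [computeSQF()].
#' @param minSignal Signal strengths at or below this value are
#'   rejected.
#' @return A list with elements `accept` (logical) and `reasons`
#'   (character vector, empty on accept).
#' @export
gateScanSet <- function(scanSet, report = computeSQF(scanSet), minSignal = 6L) {
  reasons <- character()
  if (report@sqf != 1L)
    reasons <- c(reasons, sprintf(
      "SQF = 0: center point thickness SD %.2f%% exceeds 10%%",
      report@cptSdPercent))
  if (report@minSignalStrength <= minSignal)
    reasons <- c(reasons, sprintf(
      "signal strength %d <= %d", report@minSignalStrength, minSignal))
  list(accept = length(reasons) == 0L, reasons = reasons)
}

#' Preprocess a radial scan set for reflectance analysis
#'
#' Applies, in order: complex diffusion denoising, vessel-shadow
#' detection on the denoised image, and NRPE normalization with shadow
#' columns excluded from the reference mean. Denoising precedes all
#' calculations so that speckle does not bias any metric, and shadows
#' are located before normalization so that they cannot depress the
#' reference.
#'
#' @param scanSet A [RadialScanSet-class].
#' @param denoise Logical; run the complex diffusion filter first.
#' @param iterations,timeStep,edgeThreshold Passed to
#'   [denoiseComplexDiffusion()].
#' @param thresholdFactor Passed to [detectVesselShadows()].
#' @return The scan set with normalized reflectivity and the
#'   `shadowColumns` slot filled.
#' @export
preprocessScanSet <- function(scanSet, denoise = TRUE, iterations = 10L,
                              timeStep = 0.2, edgeThreshold = 0.1,
                              thresholdFactor = 0.75) {
  for (i in seq_len(6L)) {
    scan <- scanSet@scans[[i]]
    seg <- scanSet@segmentations[[i]]
    if (denoise)
      scan@reflectivity <- pmax(denoiseComplexDiffusion(
        scan@reflectivity, iterations = iterations, timeStep = timeStep,
        edgeThreshold = edgeThreshold), 0)
    shadows <- detectVesselShadows(scan, seg, thresholdFactor)
    scan <- normalizeToRPE(scan, seg, excludedColumns = shadows)
    scanSet@scans[[i]] <- scan
    scanSet@shadowColumns[[i]] <- shadows
  }
  validObject(scanSet)
  scanSet
}
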