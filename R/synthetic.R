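#' PhantomSpec: parameters of the layered B-scan phantom
#'
#' Describes a radially symmetric macular phantom: seven layers with a
#' peripheral thickness each, the four inner layers tapering to zero
#' thickness at the foveal center with a raised-cosine pit profile;
#' per-layer base reflectivity (relative to RPE = 1); per-layer 1/f
#' axial texture with spectral exponent beta; multiplicative
#' gamma-distributed speckle; and optional vessel shadows that
#' attenuate every pixel beneath the ILM of the affected columns.
#'
#' @slot layerThicknessUm Named numeric(7), peripheral thickness per
#'   layer in micrometres.
#' @slot pitWidthMm Full width of the foveal pit taper in mm.
#' @slot layerReflectivity Named numeric(7), base normalized levels.
#' @slot layerBeta Named numeric(7), per-layer spectral exponents of
#'   the axial texture.
#' @slot textureAmplitude Relative amplitude of the 1/f texture.
#' @slot speckleShape Gamma shape of the unit-mean multiplicative
#'   speckle (larger = weaker speckle).
#' @slot shadowColumns Integer columns carrying a vessel shadow (same
#'   in every scan).
#' @slot shadowDepthFactor Multiplicative attenuation under a shadow
#'   (1 = no shadow).
#' @slot nColumns,nRows Image size.
#' @slot axialSpacingUm,lateralExtentMm Calibration.
#' @slot ilmOffsetRows Depth of the ILM below the image top, in rows.
#' @slot vitreousLevel,choroidLevel Background levels above/below the
#'   retina.
#' @slot gain Device-unit scale applied before 16-bit quantization.
#' @slot signalStrength,eyeId,subjectId,groupLabel Metadata.
#' @slot seed RNG seed; fixes the generated set bit-exactly.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    layerThicknessUm  = "numeric",
    pitWidthMm        = "numeric",
    layerReflectivity = "numeric",
    layerBeta         = "numeric",
    textureAmplitude  = "numeric",
    speckleShape      = "numeric",
    shadowColumns     = "integer",
    shadowDepthFactor = "numeric",
    nColumns          = "integer",
    nRows             = "integer",
    axialSpacingUm    = "numeric",
    lateralExtentMm   = "numeric",
    ilmOffsetRows     = "numeric",
    vitreousLevel     = "numeric",
    choroidLevel      = "numeric",
    gain              = "numeric",
    signalStrength    = "integer",
    eyeId             = "character",
    subjectId         = "character",
    groupLabel        = "character",
    seed              = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  for (sl in c("layerThicknessUm", "layerReflectivity", "layerBeta")) {
    v <- slot(object, sl)
    if (length(v) != 7L || !identical(names(v), retinalLayers()))
      return(sprintf("%s must be numeric(7) named as retinalLayers()", sl))
  }
  if (any(object@layerThicknessUm < 0)) return("layer thicknesses must be >= 0")
  if (object@pitWidthMm <= 0) return("pitWidthMm must be positive")
  if (object@speckleShape <= 0) return("speckleShape must be positive")
  if (object@shadowDepthFactor <= 0 || object@shadowDepthFactor > 1)
    return("shadowDepthFactor must be in (0, 1]")
  if (any(object@shadowColumns < 1L) ||
      any(object@shadowColumns > object@nColumns))
    return("shadowColumns outside the image")
  if (object@gain <= 0) return("gain must be positive")
  TRUE
})

#' Construct a phantom specification
#'
#' Defaults emulate a healthy macula sampled like a time-domain device:
#' 512 columns over 6 mm, 1024 axial pixels at 2 um spacing,
#' peripheral layer thicknesses near published healthy parafoveal /
#' perifoveal means, a 1.5 mm raised-cosine foveal pit for the inner
#' layers, and a handful of vessel shadows of depth factor 0.45.
#'
#' @param layerThicknessUm,pitWidthMm,layerReflectivity,layerBeta,
#'   textureAmplitude,speckleShape,shadowColumns,shadowDepthFactor,
#'   nColumns,nRows,axialSpacingUm,lateralExtentMm,ilmOffsetRows,
#'   vitreousLevel,choroidLevel,gain,signalStrength,eyeId,subjectId,
#'   groupLabel,seed See [PhantomSpec-class].
#' @return A validated [PhantomSpec-class].
#' @export
phantomSpec <- function(
    layerThicknessUm = c("RNFL" = 43, "GCL+IPL" = 66, "INL" = 40,
                         "OPL" = 37, "ONL+IS" = 85, "OS" = 15, "RPE" = 13),
    pitWidthMm = 1.5,
    layerReflectivity = c("RNFL" = 0.85, "GCL+IPL" = 0.45, "INL" = 0.30,
                          "OPL" = 0.45, "ONL+IS" = 0.22, "OS" = 0.65,
                          "RPE" = 1.00),
    layerBeta = c("RNFL" = 1.6, "GCL+IPL" = 1.2, "INL" = 1.0,
                  "OPL" = 1.1, "ONL+IS" = 0.9, "OS" = 1.3, "RPE" = 1.4),
    textureAmplitude = 0.3,
    speckleShape = 10,
    shadowColumns = c(100:104, 300:303),
    shadowDepthFactor = 0.45,
    nColumns = 512L, nRows = 1024L,
    axialSpacingUm = 2, lateralExtentMm = 6,
    ilmOffsetRows = 180,
    vitreousLevel = 0.03, choroidLevel = 0.25,
    gain = 12000,
    signalStrength = 9L,
    eyeId = "phantom", subjectId = "phantom_subject", groupLabel = "H",
    seed = 1L) {
  new("PhantomSpec",
      layerThicknessUm = layerThicknessUm[retinalLayers()],
      pitWidthMm = as.numeric(pitWidthMm),
      layerReflectivity = layerReflectivity[retinalLayers()],
      layerBeta = layerBeta[retinalLayers()],
      textureAmplitude = as.numeric(textureAmplitude),
      speckleShape = as.numeric(speckleShape),
      shadowColumns = as.integer(shadowColumns),
      shadowDepthFactor = as.numeric(shadowDepthFactor),
      nColumns = as.integer(nColumns), nRows = as.integer(nRows),
      axialSpacingUm = as.numeric(axialSpacingUm),
      lateralExtentMm = as.numeric(lateralExtentMm),
      ilmOffsetRows = as.numeric(ilmOffsetRows),
      vitreousLevel = as.numeric(vitreousLevel),
      choroidLevel = as.numeric(choroidLevel),
      gain = as.numeric(gain),
      signalStrength = as.integer(signalStrength),
      eyeId = as.character(eyeId), subjectId = as.character(subjectId),
      groupLabel = as.character(groupLabel),
      seed = as.integer(seed))
}

## raised-cosine taper: 0 at the foveal center, 1 beyond the pit radius
.pitTaper <- function(d, pitRadiusMm) {
  x <- pmin(d / pitRadiusMm, 1)
  0.5 * (1 - cos(pi * x))
}

## analytic per-column thickness (um) of one layer
.phantomThicknessUm <- function(spec, layerName, d) {
  t0 <- spec@layerThicknessUm[[layerName]]
  if (layerName %in% c("RNFL", "GCL+IPL", "INL", "OPL"))
    t0 * .pitTaper(d, spec@pitWidthMm / 2)
  else rep(t0, length(d))
}

## one column's worth of power-law noise per image column: returns an
## nRows x nCols matrix where each column is independent 1/f^beta noise
## with zero mean and unit SD
.powerLawField <- function(nRows, nCols, beta) {
  n <- nRows
  m <- seq_len(n %/% 2L)
  amp <- m^(-beta / 2)
  X <- matrix(0 + 0i, n, nCols)
  phase <- matrix(runif(length(m) * nCols, 0, 2 * pi), length(m), nCols)
  X[m + 1L, ] <- amp * exp(1i * phase)
  ## Hermitian symmetry for a real signal; the Nyquist bin must be real,
  ## so its phase degenerates to a random sign while keeping the
  ## prescribed amplitude
  if (n %% 2L == 0L) X[n %/% 2L + 1L, ] <- amp[n %/% 2L] *
      ifelse(cos(phase[n %/% 2L, ]) >= 0, 1, -1)
  conjIdx <- n - m + 1L
  keep <- conjIdx > n %/% 2L + 1L
  X[conjIdx[keep], ] <- Conj(X[m[keep] + 1L, ])
  x <- Re(mvfft(X, inverse = TRUE)) / n
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  sweep(sweep(x, 2L, colMeans(x)), 2L, sds, "/")
}

#' Generate one synthetic power-law reflectance profile
#'
#' Draws a single axial profile whose discrete Fourier amplitudes are
#' exactly `omega^(-beta/2)` with independent uniform random phases —
#' the 1D fractional-noise construction used for phantom layer texture,
#' exposed for estimator calibration.
#'
#' @param n Profile length in samples.
#' @param beta Spectral exponent; the profile's fractal dimension is
#'   `(5 - beta) / 2`.
#' @return Numeric vector of length `n` with zero mean and unit SD.
#' @export
powerLawProfile <- function(n, beta) {
  drop(.powerLawField(as.integer(n), 1L, beta))
}

#' Generate one phantom eye
#'
#' Builds the six radial B-scans of one synthetic eye from a
#' [PhantomSpec-class]: all scans share the radially symmetric layer
#' geometry; texture and speckle are drawn fresh per scan. Reflectivity
#' is `base level * (1 + amplitude * 1/f^beta texture) * speckle`,
#' clipped at zero, attenuated by the shadow depth factor beneath the
#' ILM of shadow columns, scaled by the gain and quantized to the
#' 16-bit integer grid (so a written set round-trips exactly).
#'
#' The ground-truth sidecar records the analytic per-layer/per-region
#' thickness (computed from the thickness profile, not from the image),
#' the planted shadow columns and the per-layer spectral exponents.
#'
#' @param spec A [PhantomSpec-class].
#' @return A list with elements `scanSet` ([RadialScanSet-class]) and
#'   `truth` (list: `thickness` data.frame with layer/region/value_um,
#'   `shadowColumns`, `layerBeta`, `boundaries`).
#' @export
generatePhantomEye <- function(spec) {
  validObject(spec)
  nr <- spec@nRows; nc <- spec@nColumns
  dy <- spec@axialSpacingUm
  fovea <- nc %/% 2L
  d <- abs(seq_len(nc) - fovea) * spec@lateralExtentMm / (nc - 1)

  ## boundary geometry, shared by all six scans
  thickPx <- vapply(retinalLayers(),
                    function(l) .phantomThicknessUm(spec, l, d) / dy,
                    numeric(nc))
  B <- matrix(0, 8L, nc, dimnames = list(boundaryNames(), NULL))
  B[1L, ] <- spec@ilmOffsetRows
  for (j in seq_len(7L)) B[j + 1L, ] <- B[j, ] + thickPx[, j]
  B <- round(B, 3L)   # keep boundaries on a grid that survives CSV I/O
  if (max(B) + 2 > nr)
    stop("inconsistent geometry: layers exceed the image depth")

  scanList <- withr::with_seed(spec@seed, {
    lapply(seq_len(6L), function(scanIdx) {
      base <- matrix(spec@vitreousLevel, nr, nc)
      tex <- matrix(0, nr, nc)
      for (j in seq_len(7L)) {
        field <- .powerLawField(nr, nc, spec@layerBeta[[j]])
        px <- .pixelRows(B[j, ], B[j + 1L, ])
        for (k in seq_len(nc)) {
          if (px$last[k] >= px$first[k]) {
            rows <- px$first[k]:px$last[k]
            base[rows, k] <- spec@layerReflectivity[[j]]
            tex[rows, k] <- field[rows, k]
          }
        }
      }
      pxCh <- .pixelRows(B[8L, ], rep(nr, nc))
      for (k in seq_len(nc))
        if (pxCh$last[k] >= pxCh$first[k])
          base[pxCh$first[k]:pxCh$last[k], k] <- spec@choroidLevel
      speckle <- matrix(rgamma(nr * nc, shape = spec@speckleShape,
                               rate = spec@speckleShape), nr, nc)
      img <- pmax(base * (1 + spec@textureAmplitude * tex), 0) * speckle
      if (length(spec@shadowColumns) && spec@shadowDepthFactor < 1) {
        ilmPx <- .pixelRows(B[1L, ], rep(nr, nc))
        for (k in spec@shadowColumns)
          img[ilmPx$first[k]:nr, k] <-
            img[ilmPx$first[k]:nr, k] * spec@shadowDepthFactor
      }
      raw <- pmin(round(img * spec@gain), .TIFF_MAX)
      BScan(reflectivity = raw, axialSpacingUm = dy,
            lateralExtentMm = spec@lateralExtentMm, foveaColumn = fovea,
            scanAngleDeg = (scanIdx - 1L) * 30,
            signalStrength = spec@signalStrength,
            eyeId = spec@eyeId, subjectId = spec@subjectId,
            groupLabel = spec@groupLabel)
    })
  })
  segs <- replicate(6L, LayerSegmentation(B), simplify = FALSE)

  ## analytic thickness ground truth per layer x region
  truthRows <- list()
  for (layer in analysisLayers()) {
    sub <- switch(layer, "GCC" = c("RNFL", "GCL+IPL"), layer)
    tcol <- Reduce(`+`, lapply(sub, function(l)
      .phantomThicknessUm(spec, l, d)))
    for (region in .layerRegions(layer)) {
      cols <- .regionColumns(scanList[[1L]], region,
                             innerLayer = !layer %in% .OUTER_LAYERS)
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        layer = layer, region = region,
        value_um = mean(tcol[cols]), stringsAsFactors = FALSE)
    }
  }
  list(
    scanSet = RadialScanSet(scanList, segs),
    truth = list(
      thickness = do.call(rbind, truthRows),
      shadowColumns = spec@shadowColumns,
      layerBeta = spec@layerBeta,
      boundaries = B))
}
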