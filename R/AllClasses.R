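## Central S4 containers. Conventions used throughout:
##  * reflectivity matrices are row = axial depth (row 1 nearest the
##    vitreous), column = lateral position; columns are 1-based in R.
##  * a boundary position b is measured in pixel heights from the top
##    edge of the image (b = 0 is the top edge of row 1); pixel row r
##    spans [r - 1, r), so row r belongs to the half-open boundary
##    interval [top, bottom) iff top <= r - 0.5 < bottom.

#' Names of the seven segmented intraretinal layers
#'
#' Ordered from the vitreous side outward: retinal nerve fiber layer,
#' ganglion cell + inner plexiform complex, inner nuclear layer, outer
#' plexiform layer, outer nuclear layer + inner segments, outer
#' segments, retinal pigment epithelium.
#'
#' @return Character vector of length 7.
#' @export
retinalLayers <- function() {
  c("RNFL", "GCL+IPL", "INL", "OPL", "ONL+IS", "OS", "RPE")
}

#' Names of the eight segmented layer boundaries
#'
#' @return Character vector of length 8, ordered from the inner limiting
#'   membrane to the RPE/choroid interface.
#' @export
boundaryNames <- function() {
  c("ILM", "RNFL/GCL+IPL", "GCL+IPL/INL", "INL/OPL", "OPL/ONL+IS",
    "ONL+IS/OS", "OS/RPE", "RPE/choroid")
}

## layer -> (top boundary index, bottom boundary index); GCC is the
## ganglion cell complex, the composite of RNFL and GCL+IPL.
.LAYER_BOUNDS <- list(
  "RNFL"    = c(1L, 2L),
  "GCL+IPL" = c(2L, 3L),
  "GCC"     = c(1L, 3L),
  "INL"     = c(3L, 4L),
  "OPL"     = c(4L, 5L),
  "ONL+IS"  = c(5L, 6L),
  "OS"      = c(6L, 7L),
  "RPE"     = c(7L, 8L)
)

## layers reported in the foveolar region (inner layers are displaced
## concentrically at the pit, so only the outer retina is measured there)
.OUTER_LAYERS <- c("ONL+IS", "OS", "RPE")

#' Layer names accepted by the metric functions
#'
#' The seven anatomical layers plus the GCC composite (RNFL + GCL+IPL).
#'
#' @return Character vector of length 8.
#' @export
analysisLayers <- function() names(.LAYER_BOUNDS)

#' BScan: one radial OCT cross-section with calibration
#'
#' @slot reflectivity Numeric matrix of non-negative intensities
#'   (arbitrary device units); rows are axial depth from the vitreous
#'   side, columns are lateral position.
#' @slot axialSpacingUm Micrometres per pixel row.
#' @slot lateralExtentMm Transverse scan length in millimetres.
#' @slot foveaColumn Column index (1-based) of the foveal center.
#' @slot scanAngleDeg Radial direction of this scan in degrees.
#' @slot signalStrength Device signal strength, integer 0-10.
#' @slot eyeId,subjectId,groupLabel Identifiers; `groupLabel` is one of
#'   `"H"`, `"MSON-"`, `"MSON+"` for study data but is not restricted.
#' @exportClass BScan
setClass("BScan",
  representation(
    reflectivity    = "matrix",
    axialSpacingUm  = "numeric",
    lateralExtentMm = "numeric",
    foveaColumn     = "integer",
    scanAngleDeg    = "numeric",
    signalStrength  = "integer",
    eyeId           = "character",
    subjectId       = "character",
    groupLabel      = "character"
  )
)

setValidity("BScan", function(object) {
  r <- object@reflectivity
  msg <- character()
  if (!is.numeric(r) || length(dim(r)) != 2L)
    msg <- c(msg, "reflectivity must be a numeric matrix")
  else {
    if (any(!is.finite(r))) msg <- c(msg, "reflectivity has non-finite values")
    else if (any(r < 0)) msg <- c(msg, "reflectivity has negative values")
  }
  if (length(object@axialSpacingUm) != 1L || object@axialSpacingUm <= 0)
    msg <- c(msg, "axialSpacingUm must be a single positive number")
  if (length(object@lateralExtentMm) != 1L || object@lateralExtentMm <= 0)
    msg <- c(msg, "lateralExtentMm must be a single positive number")
  if (length(object@foveaColumn) != 1L ||
      object@foveaColumn < 1L || object@foveaColumn > ncol(r))
    msg <- c(msg, "foveaColumn outside the image")
  if (length(object@signalStrength) != 1L ||
      object@signalStrength < 0L || object@signalStrength > 10L)
    msg <- c(msg, "signalStrength must be in 0..10")
  if (length(msg)) msg else TRUE
})

#' LayerSegmentation: eight boundary curves delimiting seven layers
#'
#' @slot boundaries Numeric matrix, 8 rows named as [boundaryNames()],
#'   one column per image column; entries are fractional row positions
#'   measured from the top edge of the image.
#' @exportClass LayerSegmentation
setClass("LayerSegmentation",
  representation(boundaries = "matrix")
)

setValidity("LayerSegmentation", function(object) {
  b <- object@boundaries
  if (!is.numeric(b) || nrow(b) != 8L)
    return("boundaries must be a numeric matrix with 8 rows")
  if (!identical(rownames(b), boundaryNames()))
    return("boundary rows must be named as boundaryNames(), in order")
  d <- diff(b)
  if (any(d < -1e-9)) {
    bad <- which(d < -1e-9, arr.ind = TRUE)[1L, ]
    return(sprintf(
      "boundaries not monotone at column %d (%s above %s)",
      bad[["col"]], boundaryNames()[bad[["row"]] + 1L],
      boundaryNames()[bad[["row"]]]))
  }
  TRUE
})

#' RadialScanSet: the six radial B-scans of one eye
#'
#' @slot scans List of 6 [BScan-class] objects sharing calibration.
#' @slot segmentations List of 6 matching [LayerSegmentation-class]
#'   objects.
#' @slot shadowColumns List of 6 integer vectors of vessel-shadow
#'   columns (may be empty vectors before shadow detection has run).
#' @exportClass RadialScanSet
setClass("RadialScanSet",
  representation(
    scans         = "list",
    segmentations = "list",
    shadowColumns = "list"
  )
)

setValidity("RadialScanSet", function(object) {
  if (length(object@scans) != 6L) return("a radial scan set has exactly 6 scans")
  if (length(object@segmentations) != 6L)
    return("a radial scan set has exactly 6 segmentations")
  if (!all(vapply(object@scans, is, TRUE, class2 = "BScan")))
    return("scans must all be BScan objects")
  if (!all(vapply(object@segmentations, is, TRUE, class2 = "LayerSegmentation")))
    return("segmentations must all be LayerSegmentation objects")
  dy <- vapply(object@scans, function(s) s@axialSpacingUm, 0)
  lx <- vapply(object@scans, function(s) s@lateralExtentMm, 0)
  if (length(unique(dy)) != 1L || length(unique(lx)) != 1L)
    return("all scans must share axial spacing and lateral extent")
  for (i in seq_len(6L)) {
    if (ncol(object@segmentations[[i]]@boundaries) !=
        ncol(object@scans[[i]]@reflectivity))
      return(sprintf("segmentation %d does not match scan %d in width", i, i))
  }
  if (length(object@shadowColumns) != 6L)
    return("shadowColumns must be a list of 6 integer vectors")
  TRUE
})

#' LayerROI: the pixel set of one layer in one macular region
#'
#' Built by [buildLayerROI()]; all vectors are parallel over the
#' included columns. Rows are resolved so that pixel row `r` belongs to
#' the layer iff `top <= r - 0.5 < bottom`, which makes the per-column
#' pixel counts of the seven layers partition the full retinal span.
#'
#' @slot layerName One of [analysisLayers()].
#' @slot region One of `"foveolar"`, `"foveal"`, `"parafoveal"`,
#'   `"perifoveal"`, `"across_all"`.
#' @slot columns Integer vector of included column indices (1-based).
#' @slot top,bottom Fractional boundary positions per included column.
#' @slot rowFirst,rowLast First and last pixel row per column
#'   (inclusive, 1-based).
#' @slot scanIndex Index of the source scan within its set (0 if
#'   unknown).
#' @exportClass LayerROI
setClass("LayerROI",
  representation(
    layerName = "character",
    region    = "character",
    columns   = "integer",
    top       = "numeric",
    bottom    = "numeric",
    rowFirst  = "integer",
    rowLast   = "integer",
    scanIndex = "integer"
  )
)

setValidity("LayerROI", function(object) {
  n <- length(object@columns)
  if (length(object@top) != n || length(object@bottom) != n ||
      length(object@rowFirst) != n || length(object@rowLast) != n)
    return("per-column vectors must have equal length")
  if (any(object@bottom < object@top - 1e-9))
    return("bottom boundary above top boundary")
  if (n && any(object@rowLast < object@rowFirst))
    return("empty pixel intervals must be dropped from the ROI")
  TRUE
})

#' QualityReport: scan-quality summary for one radial scan set
#'
#' @slot cptValuesUm Center-point (foveal) total retinal thickness of
#'   each of the 6 scans, in micrometres.
#' @slot cptSdPercent 100 * sample SD / mean of those values.
#' @slot sqf Scan quality factor: 1 if `cptSdPercent <= 10`, else 0.
#' @slot minSignalStrength Minimum device signal strength over the set.
#' @exportClass QualityReport
setClass("QualityReport",
  representation(
    cptValuesUm       = "numeric",
    cptSdPercent      = "numeric",
    sqf               = "integer",
    minSignalStrength = "integer"
  )
)

setValidity("QualityReport", function(object) {
  if (length(object@cptValuesUm) != 6L) return("need 6 CPT values")
  if (object@cptSdPercent < 0) return("cptSdPercent must be >= 0")
  if (!object@sqf %in% c(0L, 1L)) return("sqf must be 0 or 1")
  TRUE
})

setMethod("show", "BScan", function(object) {
  cat(sprintf(
    "BScan %s (subject %s, group %s): %d x %d px, dy = %g um, %g mm, SS = %d\n",
    object@eyeId, object@subjectId, object@groupLabel,
    nrow(object@reflectivity), ncol(object@reflectivity),
    object@axialSpacingUm, object@lateralExtentMm, object@signalStrength))
})

setMethod("show", "RadialScanSet", function(object) {
  s <- object@scans[[1L]]
  nshadow <- sum(lengths(object@shadowColumns))
  cat(sprintf(
    "RadialScanSet: eye %s, 6 scans of %d x %d px, dy = %g um, %g mm%s\n",
    s@eyeId, nrow(s@reflectivity), ncol(s@reflectivity),
    s@axialSpacingUm, s@lateralExtentMm,
    if (nshadow) sprintf(", %d shadow columns flagged", nshadow) else ""))
})

setMethod("show", "LayerROI", function(object) {
  cat(sprintf("LayerROI: %s / %s, %d columns\n",
              object@layerName, object@region, length(object@columns)))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf(
    "QualityReport: CPT sd%% = %.2f, SQF = %d, min signal strength = %d\n",
    object@cptSdPercent, object@sqf, object@minSignalStrength))
})
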