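#' Accessors for OCT containers
#'
#' Small accessor generics so downstream code never touches slots
#' directly.
#'
#' @param object A [BScan-class], [RadialScanSet-class],
#'   [LayerSegmentation-class] or [QualityReport-class] object as
#'   appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("reflectivity", function(object) standardGeneric("reflectivity"))
#' @rdname accessors
#' @export
setGeneric("reflectivity<-", function(object, value) standardGeneric("reflectivity<-"))
#' @rdname accessors
#' @export
setGeneric("boundaries", function(object) standardGeneric("boundaries"))
#' @rdname accessors
#' @export
setGeneric("axialSpacingUm", function(object) standardGeneric("axialSpacingUm"))
#' @rdname accessors
#' @export
setGeneric("lateralExtentMm", function(object) standardGeneric("lateralExtentMm"))
#' @rdname accessors
#' @export
setGeneric("foveaColumn", function(object) standardGeneric("foveaColumn"))
#' @rdname accessors
#' @export
setGeneric("signalStrength", function(object) standardGeneric("signalStrength"))
#' @rdname accessors
#' @export
setGeneric("eyeId", function(object) standardGeneric("eyeId"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setGeneric("scans", function(object) standardGeneric("scans"))
#' @rdname accessors
#' @export
setGeneric("segmentations", function(object) standardGeneric("segmentations"))
#' @rdname accessors
#' @export
setGeneric("shadowColumns", function(object) standardGeneric("shadowColumns"))
#' @rdname accessors
#' @export
setGeneric("shadowColumns<-", function(object, value) standardGeneric("shadowColumns<-"))
#' @rdname accessors
#' @export
setGeneric("sqf", function(object) standardGeneric("sqf"))

#' @rdname accessors
#' @export
setMethod("reflectivity", "BScan", function(object) object@reflectivity)

#' @rdname accessors
#' @param value Replacement value.
#' @export
setReplaceMethod("reflectivity", "BScan", function(object, value) {
  object@reflectivity <- value
  validObject(object)
  object
})

#' @rdname accessors
#' @export
setMethod("boundaries", "LayerSegmentation", function(object) object@boundaries)

#' @rdname accessors
#' @export
setMethod("axialSpacingUm", "BScan", function(object) object@axialSpacingUm)
#' @rdname accessors
#' @export
setMethod("axialSpacingUm", "RadialScanSet",
          function(object) object@scans[[1L]]@axialSpacingUm)
#' @rdname accessors
#' @export
setMethod("lateralExtentMm", "BScan", function(object) object@lateralExtentMm)
#' @rdname accessors
#' @export
setMethod("foveaColumn", "BScan", function(object) object@foveaColumn)
#' @rdname accessors
#' @export
setMethod("signalStrength", "BScan", function(object) object@signalStrength)
#' @rdname accessors
#' @export
setMethod("eyeId", "BScan", function(object) object@eyeId)
#' @rdname accessors
#' @export
setMethod("eyeId", "RadialScanSet", function(object) object@scans[[1L]]@eyeId)
#' @rdname accessors
#' @export
setMethod("subjectId", "BScan", function(object) object@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectId", "RadialScanSet",
          function(object) object@scans[[1L]]@subjectId)
#' @rdname accessors
#' @export
setMethod("groupLabel", "BScan", function(object) object@groupLabel)
#' @rdname accessors
#' @export
setMethod("groupLabel", "RadialScanSet",
          function(object) object@scans[[1L]]@groupLabel)
#' @rdname accessors
#' @export
setMethod("scans", "RadialScanSet", function(object) object@scans)
#' @rdname accessors
#' @export
setMethod("segmentations", "RadialScanSet", function(object) object@segmentations)
#' @rdname accessors
#' @export
setMethod("shadowColumns", "RadialScanSet", function(object) object@shadowColumns)
#' @rdname accessors
#' @export
setReplaceMethod("shadowColumns", "RadialScanSet", function(object, value) {
  object@shadowColumns <- lapply(value, as.integer)
  validObject(object)
  object
})
#' @rdname accessors
#' @export
setMethod("sqf", "QualityReport", function(object) object@sqf)
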