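#' Construct a BScan
#'
#' @param reflectivity Non-negative numeric matrix (rows = axial depth
#'   from the vitreous side, columns = lateral position).
#' @param axialSpacingUm Micrometres per row.
#' @param lateralExtentMm Transverse scan length in mm.
#' @param foveaColumn 1-based column index of the foveal center.
#' @param scanAngleDeg Radial direction of the scan.
#' @param signalStrength Integer 0-10.
#' @param eyeId,subjectId,groupLabel Identifiers.
#' @return A validated [BScan-class].
#' @export
BScan <- function(reflectivity, axialSpacingUm, lateralExtentMm,
                  foveaColumn, scanAngleDeg = 0, signalStrength = 10L,
                  eyeId = "eye", subjectId = "subject", groupLabel = "H") {
  new("BScan",
      reflectivity    = reflectivity,
      axialSpacingUm  = as.numeric(axialSpacingUm),
      lateralExtentMm = as.numeric(lateralExtentMm),
      foveaColumn     = as.integer(foveaColumn),
      scanAngleDeg    = as.numeric(scanAngleDeg),
      signalStrength  = as.integer(signalStrength),
      eyeId           = as.character(eyeId),
      subjectId       = as.character(subjectId),
      groupLabel      = as.character(groupLabel))
}

#' Construct a LayerSegmentation
#'
#' @param boundaries Numeric 8 x n_columns matrix of fractional row
#'   positions (0 = top edge of the image). Row names, if absent, are
#'   set to [boundaryNames()].
#' @return A validated [LayerSegmentation-class].
#' @export
LayerSegmentation <- function(boundaries) {
  if (is.null(rownames(boundaries))) rownames(boundaries) <- boundaryNames()
  new("LayerSegmentation", boundaries = boundaries)
}

#' Construct a RadialScanSet
#'
#' @param scans List of 6 [BScan-class] objects.
#' @param segmentations List of 6 [LayerSegmentation-class] objects.
#' @param shadowColumns Optional list of 6 integer vectors of
#'   vessel-shadow columns; defaults to empty.
#' @return A validated [RadialScanSet-class].
#' @export
RadialScanSet <- function(scans, segmentations,
                          shadowColumns = rep(list(integer()), 6L)) {
  new("RadialScanSet", scans = scans, segmentations = segmentations,
      shadowColumns = lapply(shadowColumns, as.integer))
}

## ---------------------------------------------------------------------
## Macular region geometry

## half-open radial annuli [inner, outer) in mm; diameters 0.375, 1.85,
## 2.85 and 5.85 mm
.REGION_RADII <- data.frame(
  region   = c("foveolar", "foveal", "parafoveal", "perifoveal"),
  inner_mm = c(0, 0.1875, 0.925, 1.425),
  outer_mm = c(0.1875, 0.925, 1.425, 2.925),
  stringsAsFactors = FALSE
)

#' Macular region definitions
#'
#' Four concentric zones centred on the fovea: the foveolar disc
#' (diameter 0.375 mm) and the foveal, parafoveal and perifoveal annuli
#' (outer diameters 1.85, 2.85 and 5.85 mm). Radial intervals are
#' half-open `[inner, outer)`.
#'
#' @return A data.frame with columns `region`, `inner_mm`, `outer_mm`
#'   (radii in millimetres).
#' @export
macularRegions <- function() .REGION_RADII

#' Assign an image column to a macular region
#'
#' The radial distance of a column from the foveal center is
#' `d = |column - foveaColumn| * lateralExtentMm / (nColumns - 1)`;
#' the column falls in the half-open annulus containing `d`, or in no
#' region when `d >= 2.925` mm (outside the perifoveal ring).
#'
#' @param column Column index (1-based); may be a vector.
#' @param foveaColumn 1-based foveal center column.
#' @param lateralExtentMm Transverse scan length in mm.
#' @param nColumns Number of image columns.
#' @return Character vector of region names, `NA` outside all regions.
#' @export
regionOfColumn <- function(column, foveaColumn, lateralExtentMm, nColumns) {
  stopifnot(all(column >= 1L), all(column <= nColumns), nColumns > 1L)
  d <- abs(column - foveaColumn) * lateralExtentMm / (nColumns - 1)
  out <- rep(NA_character_, length(d))
  for (i in seq_len(nrow(.REGION_RADII))) {
    hit <- d >= .REGION_RADII$inner_mm[i] & d < .REGION_RADII$outer_mm[i]
    out[hit] <- .REGION_RADII$region[i]
  }
  out
}

## columns of a scan falling in a named region ("across_all" = union of
## the four zones, restricted to the annuli for inner layers)
.regionColumns <- function(scan, region, innerLayer) {
  nc <- ncol(scan@reflectivity)
  assigned <- regionOfColumn(seq_len(nc), scan@foveaColumn,
                             scan@lateralExtentMm, nc)
  if (region == "across_all") {
    keep <- if (innerLayer) {
      assigned %in% c("foveal", "parafoveal", "perifoveal")
    } else !is.na(assigned)
  } else {
    keep <- !is.na(assigned) & assigned == region
  }
  which(keep)
}

## resolve a fractional half-open boundary interval [top, bottom) to
## inclusive 1-based pixel rows; pixel r belongs iff top <= r - 0.5 < bottom
.pixelRows <- function(top, bottom) {
  first <- ceiling(top + 0.5)
  last  <- ceiling(bottom + 0.5) - 1
  list(first = as.integer(first), last = as.integer(last))
}

#' Build the pixel region of one layer within one macular region
#'
#' Collects, for one scan, the per-column boundary interval of a layer
#' restricted to the columns of a macular region, after removing
#' excluded (vessel-shadow) columns and columns where the resolved
#' pixel interval is empty. By design the inner layers (RNFL, GCL+IPL,
#' GCC, INL, OPL) are not measured in the foveolar region, where they
#' are displaced concentrically: requesting such a combination returns
#' an empty ROI. For `region = "across_all"` the ROI is the union of
#' the regions in which the layer is measured.
#'
#' @param scan A [BScan-class].
#' @param segmentation Matching [LayerSegmentation-class].
#' @param layerName One of [analysisLayers()] (`"GCC"` spans the ILM to
#'   the GCL+IPL/INL boundary).
#' @param region Region name, or `"across_all"`.
#' @param excludedColumns Integer vector of columns to drop (e.g.
#'   vessel shadows).
#' @param scanIndex Stored in the ROI for provenance.
#' @return A [LayerROI-class]; possibly with zero columns.
#' @export
buildLayerROI <- function(scan, segmentation, layerName, region,
                          excludedColumns = integer(), scanIndex = 0L) {
  if (!layerName %in% names(.LAYER_BOUNDS))
    stop("unknown layer name: ", layerName)
  stopifnot(region %in% c(.REGION_RADII$region, "across_all"))
  inner <- !layerName %in% .OUTER_LAYERS
  emptyROI <- function() new("LayerROI", layerName = layerName,
                             region = region, columns = integer(),
                             top = numeric(), bottom = numeric(),
                             rowFirst = integer(), rowLast = integer(),
                             scanIndex = as.integer(scanIndex))
  if (inner && region == "foveolar") return(emptyROI())
  cols <- .regionColumns(scan, region, inner)
  cols <- setdiff(cols, as.integer(excludedColumns))
  if (!length(cols)) return(emptyROI())
  bidx <- .LAYER_BOUNDS[[layerName]]
  b <- segmentation@boundaries
  top <- b[bidx[1L], cols]
  bottom <- b[bidx[2L], cols]
  px <- .pixelRows(top, bottom)
  keep <- px$last >= px$first   # drop zero-height columns
  new("LayerROI",
      layerName = layerName, region = region,
      columns = as.integer(cols[keep]),
      top = unname(top[keep]), bottom = unname(bottom[keep]),
      rowFirst = px$first[keep], rowLast = px$last[keep],
      scanIndex = as.integer(scanIndex))
}

## pull the ROI's pixel values out of a reflectivity matrix, as a list
## of per-column profiles (vitreous side first)
.roiProfiles <- function(roi, reflectivity) {
  lapply(seq_along(roi@columns), function(i) {
    reflectivity[roi@rowFirst[i]:roi@rowLast[i], roi@columns[i]]
  })
}

## ---------------------------------------------------------------------
## File I/O. Interchange format of one eye (one directory):
##   <eye>_scan<k>.tif             16-bit grayscale reflectivity, k = 0..5
##   <eye>_scan<k>_boundaries.csv  header scan,column,boundary,row
##   <eye>_metadata.json           calibration and identifiers
## On disk, column and fovea_column are 0-based and row positions are
## fractional rows from the image top, matching the in-memory boundary
## convention.

.TIFF_MAX <- 65535

#' Write a radial scan set to a directory
#'
#' Writes six 16-bit grayscale TIFFs, six boundary CSVs (header
#' `scan,column,boundary,row`, 0-based columns) and one metadata JSON
#' (`axial_spacing_um`, `lateral_extent_mm`, `fovea_column` 0-based,
#' `signal_strength`, `eye_id`, `subject_id`, `group`). Reflectivity
#' values must already lie on the 16-bit integer grid `0..65535`.
#'
#' @param scanSet A [RadialScanSet-class].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @seealso [readScanSet()]
#' @export
writeScanSet <- function(scanSet, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  eye <- eyeId(scanSet)
  for (k in 0:5) {
    scan <- scanSet@scans[[k + 1L]]
    r <- scan@reflectivity
    if (max(r) > .TIFF_MAX || any(abs(r - round(r)) > 1e-6))
      stop("reflectivity must be 16-bit integers (0..65535) for TIFF output")
    tiff::writeTIFF(r / .TIFF_MAX,
                    file.path(dir, sprintf("%s_scan%d.tif", eye, k)),
                    bits.per.sample = 16L, compression = "none")
    b <- scanSet@segmentations[[k + 1L]]@boundaries
    tab <- data.frame(
      scan = k,
      column = rep(seq_len(ncol(b)) - 1L, each = 8L),
      boundary = rep(boundaryNames(), times = ncol(b)),
      row = as.vector(b),
      stringsAsFactors = FALSE)
    write.csv(tab, file.path(dir, sprintf("%s_scan%d_boundaries.csv", eye, k)),
              row.names = FALSE)
  }
  s1 <- scanSet@scans[[1L]]
  meta <- list(
    axial_spacing_um  = s1@axialSpacingUm,
    lateral_extent_mm = s1@lateralExtentMm,
    fovea_column      = s1@foveaColumn - 1L,
    scan_angles_deg   = vapply(scanSet@scans, function(s) s@scanAngleDeg, 0),
    signal_strength   = min(vapply(scanSet@scans, function(s) s@signalStrength, 0L)),
    eye_id            = s1@eyeId,
    subject_id        = s1@subjectId,
    group             = s1@groupLabel)
  jsonlite::write_json(meta, file.path(dir, sprintf("%s_metadata.json", eye)),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a radial scan set from a directory
#'
#' Expects the layout produced by [writeScanSet()]. Boundary
#' monotonicity is validated on read; a violation is reported with the
#' scan and 0-based column at fault.
#'
#' @param dir Directory holding 6 TIFFs, 6 boundary CSVs and one
#'   metadata JSON.
#' @return A validated [RadialScanSet-class].
#' @export
readScanSet <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  jsons <- list.files(dir, pattern = "_metadata\\.json$", full.names = TRUE)
  if (length(jsons) != 1L)
    stop("expected exactly one *_metadata.json in ", dir)
  meta <- jsonlite::read_json(jsons, simplifyVector = TRUE)
  eye <- meta$eye_id
  angles <- meta$scan_angles_deg
  if (is.null(angles)) angles <- seq(0, 150, by = 30)
  scans <- vector("list", 6L)
  segs <- vector("list", 6L)
  for (k in 0:5) {
    tifPath <- file.path(dir, sprintf("%s_scan%d.tif", eye, k))
    csvPath <- file.path(dir, sprintf("%s_scan%d_boundaries.csv", eye, k))
    if (!file.exists(tifPath)) stop("missing scan file: ", tifPath)
    if (!file.exists(csvPath)) stop("missing boundary file: ", csvPath)
    img <- tiff::readTIFF(tifPath)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    r <- round(img * .TIFF_MAX)
    tab <- read.csv(csvPath, stringsAsFactors = FALSE)
    need <- c("scan", "column", "boundary", "row")
    if (!all(need %in% names(tab)))
      stop("boundary CSV ", csvPath, " lacks columns ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    b <- matrix(NA_real_, 8L, ncol(r), dimnames = list(boundaryNames(), NULL))
    bi <- match(tab$boundary, boundaryNames())
    if (anyNA(bi)) stop("unknown boundary name in ", csvPath)
    b[cbind(bi, tab$column + 1L)] <- tab$row
    if (anyNA(b)) stop("incomplete boundary table in ", csvPath)
    d <- diff(b)
    if (any(d < -1e-9)) {
      bad <- which(d < -1e-9, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "non-monotone boundaries in scan %d at column %d (%s above %s)",
        k, bad[["col"]] - 1L, boundaryNames()[bad[["row"]] + 1L],
        boundaryNames()[bad[["row"]]]))
    }
    scans[[k + 1L]] <- BScan(
      reflectivity    = r,
      axialSpacingUm  = meta$axial_spacing_um,
      lateralExtentMm = meta$lateral_extent_mm,
      foveaColumn     = meta$fovea_column + 1L,
      scanAngleDeg    = angles[k + 1L],
      signalStrength  = meta$signal_strength,
      eyeId           = meta$eye_id,
      subjectId       = meta$subject_id,
      groupLabel      = meta$group)
    segs[[k + 1L]] <- LayerSegmentation(b)
  }
  RadialScanSet(scans, segs)
}

#' Write / read a feature table
#'
#' Long-format CSV with columns
#' `eye, subject, group, layer, region, metric, value`.
#'
#' @param table A feature table data.frame.
#' @param path File path.
#' @return `writeFeatureTable` returns `path` invisibly;
#'   `readFeatureTable` returns the data.frame.
#' @export
writeFeatureTable <- function(table, path) {
  need <- c("eye", "subject", "group", "layer", "region", "metric", "value")
  stopifnot(all(need %in% names(table)))
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
    stop("cannot write feature table to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  write.csv(table[, need], con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(eye = "character", subject = "character",
                          group = "character", layer = "character",
                          region = "character", metric = "character",
                          value = "numeric"))
}
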