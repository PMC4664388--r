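test_that("columns partition into the four concentric macular regions", {
  set.seed(101)
  for (rep in 1:20) {
    nCols <- sample(40:600, 1)
    fovea <- sample(seq_len(nCols), 1)
    extent <- runif(1, 4, 8)
    cols <- seq_len(nCols)
    reg <- regionOfColumn(cols, fovea, extent, nCols)
    d <- abs(cols - fovea) * extent / (nCols - 1)
    # inside the perifoveal ring every column has exactly one region
    expect_true(all(!is.na(reg[d < 2.925])))
    expect_true(all(is.na(reg[d >= 2.925])))
    # spot-check the annulus edges (half-open intervals)
    expect_identical(unname(reg[d < 0.1875][1]), "foveolar")
  }
  # stated geometry: d = 0 foveolar, d = 1.0 parafoveal, d = 2.95 outside
  nCols <- 601; extent <- 6; fovea <- 301   # 0.01 mm per column step
  dOf <- function(k) abs(k - fovea) * extent / (nCols - 1)
  kAt <- function(d) fovea + round(d * (nCols - 1) / extent)
  expect_equal(regionOfColumn(fovea, fovea, extent, nCols), "foveolar")
  expect_equal(dOf(kAt(1.0)), 1.0)
  expect_equal(regionOfColumn(kAt(1.0), fovea, extent, nCols), "parafoveal")
  expect_equal(dOf(kAt(2.95)), 2.95)
  expect_true(is.na(regionOfColumn(kAt(2.95), fovea, extent, nCols)))
})

test_that("pixel intervals of the seven layers partition the retinal span", {
  set.seed(202)
  scanSet <- uniformScanSet()
  scan <- scans(scanSet)[[1]]
  for (rep in 1:30) {
    # random fractional monotone boundaries in one column
    b <- sort(runif(8, 5, 100))
    B <- matrix(rep(b, 5), nrow = 8,
                dimnames = list(boundaryNames(), NULL))
    seg <- LayerSegmentation(B)
    counts <- vapply(retinalLayers(), function(l) {
      roi <- buildLayerROI(BScan(matrix(1, 120, 5), 2, 6, 3), seg, l,
                           "across_all")
      if (!length(roi@columns)) 0L else roi@rowLast[1] - roi@rowFirst[1] + 1L
    }, 0L)
    total <- ceiling(b[8] + 0.5) - ceiling(b[1] + 0.5)
    expect_identical(sum(counts), as.integer(total))
    # fractional heights telescope exactly
    expect_equal(sum(diff(b)), b[8] - b[1])
  }
})

test_that("layer ROIs respect composites, exclusions and the foveolar rule", {
  scanSet <- uniformScanSet()
  scan <- scans(scanSet)[[1]]
  seg <- segmentations(scanSet)[[1]]
  # inner layers are not measured in the foveolar disc
  for (l in c("RNFL", "GCL+IPL", "GCC", "INL", "OPL"))
    expect_length(buildLayerROI(scan, seg, l, "foveolar")@columns, 0L)
  expect_gt(length(buildLayerROI(scan, seg, "ONL+IS", "foveolar")@columns), 0L)
  # GCC spans ILM to the GCL+IPL/INL boundary
  gcc <- buildLayerROI(scan, seg, "GCC", "parafoveal")
  b <- boundaries(seg)
  expect_equal(unique(gcc@top), unname(b["ILM", 1]))
  expect_equal(unique(gcc@bottom), unname(b["GCL+IPL/INL", 1]))
  # excluding every region column yields an empty ROI, not an error
  para <- buildLayerROI(scan, seg, "RNFL", "parafoveal")
  expect_gt(length(para@columns), 0L)
  empty <- buildLayerROI(scan, seg, "RNFL", "parafoveal",
                         excludedColumns = para@columns)
  expect_length(empty@columns, 0L)
  expect_error(buildLayerROI(scan, seg, "NFL", "foveal"), "unknown layer")
})

test_that("a phantom eye round-trips through the directory format", {
  ph <- generatePhantomEye(smallPhantomSpec(seed = 31L))
  dir <- withr::local_tempdir()
  writeScanSet(ph$scanSet, dir)
  back <- readScanSet(dir)
  for (i in 1:6) {
    expect_identical(reflectivity(scans(back)[[i]]),
                     unname(reflectivity(scans(ph$scanSet)[[i]])))
    expect_identical(boundaries(segmentations(back)[[i]]),
                     boundaries(segmentations(ph$scanSet)[[i]]))
  }
  s <- scans(back)[[1]]
  expect_identical(axialSpacingUm(s), 2)          # stated pixel spacing
  expect_identical(foveaColumn(s), foveaColumn(scans(ph$scanSet)[[1]]))
  expect_identical(eyeId(back), eyeId(ph$scanSet))
  expect_identical(groupLabel(back), groupLabel(ph$scanSet))
})

test_that("missing files and non-monotone boundaries fail loudly on read", {
  ph <- generatePhantomEye(smallPhantomSpec(seed = 32L))
  dir <- withr::local_tempdir()
  writeScanSet(ph$scanSet, dir)
  # missing scan file is named in the error
  tif3 <- file.path(dir, "phantom_scan3.tif")
  file.rename(tif3, paste0(tif3, ".bak"))
  expect_error(readScanSet(dir), "phantom_scan3.tif")
  file.rename(paste0(tif3, ".bak"), tif3)
  # swap OS/RPE above ONL+IS/OS at (0-based) column 40 of scan 2
  csv <- file.path(dir, "phantom_scan2_boundaries.csv")
  tab <- read.csv(csv)
  iHi <- which(tab$column == 40 & tab$boundary == "OS/RPE")
  iLo <- which(tab$column == 40 & tab$boundary == "ONL+IS/OS")
  tab$row[c(iHi, iLo)] <- tab$row[c(iLo, iHi)] + c(-8, 8)
  write.csv(tab, csv, row.names = FALSE)
  expect_error(readScanSet(dir), "scan 2 at column 40")
})

test_that("feature tables round-trip through CSV", {
  ft <- data.frame(
    eye = c("e1", "e1", "e2"), subject = c("s1", "s1", "s2"),
    group = c("H", "H", "MSON+"), layer = c("RNFL", "GCC", "RNFL"),
    region = "across_all",
    metric = c("thickness_um", "contrast_au", "fractal_dimension_au"),
    value = c(38.16, 3093.25, NA), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(ft, path)
  back <- readFeatureTable(path)
  expect_equal(back, ft)
  expect_error(writeFeatureTable(ft, file.path(withr::local_tempdir(),
                                               "no/such/dir/x.csv")),
               "cannot write")
})
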