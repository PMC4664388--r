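test_that("mean thickness is the boundary distance times pixel spacing", {
  roi <- blockROI(rows = 3:21, cols = 1:10)      # 19 rows per column
  expect_equal(layerThickness(roi, 2)$value, 38)  # healthy RNFL scale
  twoCol <- new("LayerROI", layerName = "RNFL", region = "across_all",
                columns = 1:2, top = c(0, 0), bottom = c(10, 20),
                rowFirst = c(1L, 1L), rowLast = c(10L, 20L), scanIndex = 0L)
  expect_equal(layerThickness(twoCol, 2)$value, 30)
  empty <- buildLayerROI(matScan(matrix(1, 20, 20)),
                         LayerSegmentation(matrix(5, 8, 20)),
                         "RNFL", "across_all")
  res <- layerThickness(empty, 2)
  expect_true(is.na(res$value))
  expect_identical(res$n, 0L)
})

test_that("GLCM contrast matches closed forms and brute-force enumeration", {
  # constant ROI: all co-occurring pairs identical
  const <- matScan(matrix(500, 16, 16))
  roi <- blockROI(2:15, 2:15)
  expect_equal(glcmContrast(roi, const)$value, 0)

  # two-level vertical stripes, horizontal offset only: contrast (L-1)^2
  stripes <- matrix(0, 16, 16)
  stripes[, seq(2, 16, by = 2)] <- 1000
  sc <- matScan(stripes)
  got <- glcmContrast(blockROI(1:16, 1:16), sc, nLevels = 64,
                      offsets = list(c(0L, 1L)))
  expect_equal(got$value, 63^2)

  # checkerboard has more contrast than a constant
  chk <- matrix(0, 16, 16)
  chk[(row(chk) + col(chk)) %% 2 == 0] <- 800
  expect_gt(glcmContrast(blockROI(1:16, 1:16), matScan(chk))$value, 0)

  # exact agreement with pair enumeration on random ragged ROIs
  set.seed(33)
  offs <- list(c(0L, 1L), c(1L, 0L))
  for (rep in 1:10) {
    m <- matrix(runif(32 * 32, 0, 4000), 32, 32)
    sc <- matScan(m)
    cols <- 4:28
    tops <- sample(2:10, length(cols), replace = TRUE)
    bots <- tops + sample(3:18, length(cols), replace = TRUE)
    roi <- new("LayerROI", layerName = "INL", region = "across_all",
               columns = as.integer(cols), top = tops - 1, bottom = bots,
               rowFirst = as.integer(tops), rowLast = as.integer(bots),
               scanIndex = 0L)
    hi <- quantile(m, 0.99, names = FALSE)
    lv <- matrix(NA_real_, 32, 32)
    for (i in seq_along(cols))
      lv[tops[i]:bots[i], cols[i]] <-
        quantizeLevels(m[tops[i]:bots[i], cols[i]], 64, hi)
    expect_equal(glcmContrast(roi, sc)$value, bruteContrast(lv, offs))
  }
})

test_that("spectral-slope FD recovers the generating exponent", {
  set.seed(44)
  fd2 <- mean(replicate(50, profileFractalDimension(powerLawProfile(64, 2))))
  expect_equal(fd2, 1.5, tolerance = 0.05)
  fd0 <- mean(replicate(50, profileFractalDimension(powerLawProfile(64, 0))))
  expect_equal(fd0, 2.5, tolerance = 0.05)
  # gain invariance: log-spectrum shifts by a constant, slope unchanged
  p <- powerLawProfile(64, 1.3)
  for (c in c(0.1, 3.7, 40))
    expect_equal(profileFractalDimension(c * p),
                 profileFractalDimension(p), tolerance = 1e-9)
  # degenerate profiles
  expect_true(is.na(profileFractalDimension(rep(1, 64))))   # zero variance
  expect_true(is.na(profileFractalDimension(rnorm(4))))     # too short
})

test_that("total reflectance and layer index match direct column sums", {
  # uniform ROI: 20 pixels of 0.5 per column -> TR = 10 -> 10 dB
  u <- matScan(matrix(0.5, 30, 10))
  roi20 <- blockROI(4:23, 1:10)
  expect_equal(totalReflectance(roi20, u)$value, 10)
  # doubling the height at fixed mean reflectance adds 10 log10(2) dB
  u2 <- matScan(matrix(0.5, 60, 10))
  roi40 <- blockROI(4:43, 1:10)
  expect_equal(totalReflectance(roi40, u2)$value - 10, 10 * log10(2),
               tolerance = 1e-9)
  # column whose pixels all equal I_sa, height 30 -> LI = 30
  m <- matrix(700, 40, 10)
  expect_equal(layerIndex(blockROI(5:34, 1:10), matScan(m))$value, 30)

  # oracle: sums and MR_k * H_k agree on random phantoms
  set.seed(55)
  for (rep in 1:50) {
    nr <- sample(20:40, 1); nc <- sample(8:20, 1)
    m <- matrix(runif(nr * nc, 0, 3), nr, nc)
    sc <- matScan(m)
    cols <- seq_len(nc)
    tops <- sample(1:5, nc, replace = TRUE)
    bots <- tops + sample(4:12, nc, replace = TRUE)
    bots <- pmin(bots, nr)
    roi <- new("LayerROI", layerName = "OPL", region = "across_all",
               columns = as.integer(cols), top = tops - 1, bottom = bots,
               rowFirst = as.integer(tops), rowLast = as.integer(bots),
               scanIndex = 0L)
    trOracle <- vapply(seq_len(nc), function(k) {
      v <- m[tops[k]:bots[k], k]
      mean(v) * length(v)                     # MR_k * (H_k in pixels)
    }, 0)
    expect_equal(totalReflectance(roi, sc)$value,
                 10 * log10(mean(trOracle)), tolerance = 1e-9)
    isa <- quantile(m, 0.99, names = FALSE)
    expect_equal(layerIndex(roi, sc)$value, mean(trOracle / isa),
                 tolerance = 1e-9)
  }
  # TR in dB is strictly increasing in layer height at fixed reflectance
  heights <- c(5, 10, 20, 40)
  trs <- vapply(heights, function(h)
    totalReflectance(blockROI(1:h, 1:10), matScan(matrix(0.5, 60, 10)))$value,
    0)
  expect_true(all(diff(trs) > 0))
})

test_that("the per-eye feature table honours layout and ground truth", {
  ph <- cachedPhantom()
  ft <- cachedFeatures()
  # foveolar rows exist only for the outer retinal layers
  fov <- unique(ft$layer[ft$region == "foveolar"])
  expect_setequal(fov, c("ONL+IS", "OS", "RPE"))
  # thickness matches the analytic ground truth within one pixel (2 um)
  th <- merge(ft[ft$metric == "thickness_um", ], ph$truth$thickness,
              by = c("layer", "region"))
  expect_true(all(abs(th$value - th$value_um) <= 2))
  # GCC thickness equals RNFL + GCL+IPL per region
  for (reg in c("foveal", "parafoveal", "perifoveal", "across_all")) {
    pick <- function(l) ft$value[ft$metric == "thickness_um" &
                                 ft$layer == l & ft$region == reg]
    expect_equal(pick("GCC"), pick("RNFL") + pick("GCL+IPL"),
                 tolerance = 1e-9)
  }
  # every permitted cell has all five metrics; the only undefined values
  # are the fractal dimension of the RPE, whose ~6.5-pixel profiles fall
  # below the 8-sample minimum at 2 um axial sampling
  undef <- ft[is.na(ft$value), ]
  expect_true(all(undef$metric == "fractal_dimension_au" &
                  undef$layer == "RPE"))
  expect_identical(sort(unique(ft$metric)), sort(metricNames()))
})

test_that("phantom layer FD ordering follows the planted spectral exponents", {
  # distinct exponents on a reduced phantom in the texture-dominated
  # regime (negligible speckle): white speckle flattens the steepest
  # spectra and would mask the ordering that the texture knob plants
  betas <- c("RNFL" = 2.2, "GCL+IPL" = 1.7, "INL" = 1.2, "OPL" = 0.7,
             "ONL+IS" = 1.0, "OS" = 1.5, "RPE" = 2.0)
  thick <- setNames(rep(60, 7), retinalLayers())  # equal profile lengths
  fdSum <- setNames(numeric(7), retinalLayers())
  nEyes <- 20
  for (e in seq_len(nEyes)) {
    ph <- generatePhantomEye(phantomSpec(
      nColumns = 128L, nRows = 512L, ilmOffsetRows = 40,
      layerThicknessUm = thick, layerBeta = betas,
      textureAmplitude = 0.5, speckleShape = 40000,
      shadowColumns = integer(), seed = 7000L + e))
    ss <- ph$scanSet
    for (i in 1:6) {
      scan <- scans(ss)[[i]]; seg <- segmentations(ss)[[i]]
      scan <- normalizeToRPE(scan, seg)
      for (l in retinalLayers()) {
        roi <- buildLayerROI(scan, seg, l, "across_all")
        fdSum[l] <- fdSum[l] + fractalDimension(roi, scan)$value
      }
    }
  }
  fdMean <- fdSum / (6 * nEyes)
  ord <- order(betas, decreasing = TRUE)
  # larger beta -> smaller FD, monotone across the seven layers
  expect_true(all(diff(fdMean[ord]) > 0))
})
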