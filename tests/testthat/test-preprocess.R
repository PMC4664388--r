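test_that("complex diffusion smooths noise but keeps edges and the mean", {
  # a constant image has no gradients to diffuse
  const <- matrix(77, 40, 40)
  expect_identical(denoiseComplexDiffusion(const), const)
  # zero iterations is the identity
  set.seed(11)
  img <- matrix(runif(1600, 50, 150), 40, 40)
  expect_identical(denoiseComplexDiffusion(img, iterations = 0), img)
  expect_error(denoiseComplexDiffusion(matrix(c(1, NA, 3, 4), 2)),
               "non-finite")

  # step edge + noise: off-edge variance drops, edge stays put, mean kept
  set.seed(12)
  step <- matrix(100, 64, 64)
  step[, 33:64] <- 200
  noisy <- step + matrix(rnorm(64 * 64, 0, 8), 64, 64)
  den <- denoiseComplexDiffusion(noisy, iterations = 10)
  flat <- 1:24   # columns well away from the edge
  expect_lt(var(as.vector(den[, flat])), var(as.vector(noisy[, flat])))
  edgeCol <- function(m) which.max(abs(diff(colMeans(m))))
  expect_identical(edgeCol(den), edgeCol(noisy))
  expect_lt(abs(mean(den) - mean(noisy)) / mean(noisy), 0.05)
})

test_that("the shadowgram flags planted vessel shadows and nothing else", {
  spec <- phantomSpec(shadowColumns = c(100:104, 300:303),
                      shadowDepthFactor = 0.45, seed = 41L)
  ph <- generatePhantomEye(spec)
  scan <- scans(ph$scanSet)[[1]]
  seg <- segmentations(ph$scanSet)[[1]]
  # detection runs on the denoised image, as in the pipeline
  reflectivity(scan) <- pmax(denoiseComplexDiffusion(reflectivity(scan)), 0)
  flagged <- detectVesselShadows(scan, seg, thresholdFactor = 0.75)
  truth <- spec@shadowColumns
  expect_true(all(truth %in% flagged))            # recall 1
  spurious <- setdiff(flagged, truth)
  # spurious columns only hug the shadow edges: the one-column dilation
  # plus the lateral blur halo of the diffusion filter (~2 px std after
  # 10 steps of 0.2), never free-standing false detections
  expect_true(all(vapply(spurious,
                         function(k) min(abs(k - truth)) <= 4, TRUE)))
  expect_lte(length(spurious), 0.01 * 512 + 2 * 2)

  # no shadows planted -> nothing flagged
  clean <- uniformScanSet()
  expect_identical(
    detectVesselShadows(scans(clean)[[1]], segmentations(clean)[[1]]),
    integer())
  # all-zero image: degenerate shadowgram, empty set with a warning
  zero <- BScan(matrix(0, 120, 49), 2, 6, 25)
  expect_warning(
    out <- detectVesselShadows(zero, segmentations(clean)[[1]]),
    "no signal")
  expect_identical(out, integer())
})

test_that("NRPE normalization divides by the RPE mean and is idempotent", {
  ss <- uniformScanSet()    # RPE level 1000 everywhere
  scan <- scans(ss)[[1]]
  seg <- segmentations(ss)[[1]]
  norm1 <- normalizeToRPE(scan, seg)
  expect_equal(reflectivity(norm1), reflectivity(scan) / 1000)
  # the output's RPE band has mean 1
  rpe <- buildLayerROI(norm1, seg, "RPE", "across_all")
  vals <- unlist(lapply(seq_along(rpe@columns), function(i)
    reflectivity(norm1)[rpe@rowFirst[i]:rpe@rowLast[i], rpe@columns[i]]))
  expect_equal(mean(vals), 1, tolerance = 1e-9)
  # idempotence
  norm2 <- normalizeToRPE(norm1, seg)
  expect_equal(reflectivity(norm2), reflectivity(norm1), tolerance = 1e-12)
  # global gain cancels
  scaled <- scan
  reflectivity(scaled) <- reflectivity(scan) * 3.7
  expect_equal(reflectivity(normalizeToRPE(scaled, seg)),
               reflectivity(norm1), tolerance = 1e-12)
  # no reference signal
  zero <- BScan(matrix(0, 120, 49), 2, 6, 25)
  expect_error(normalizeToRPE(zero, seg), "no reference signal")
})

test_that("SQF follows the percent-SD-of-CPT rule", {
  mkSet <- function(cptsUm) {
    # CPT = (sum of the six inner heights) * dy; vary ONL+IS to hit targets
    base <- c("RNFL" = 10, "GCL+IPL" = 15, "INL" = 8, "OPL" = 8,
              "ONL+IS" = 45, "OS" = 14, "RPE" = 10)
    uniformScanSet(nRows = 160L, perScanHeights = lapply(cptsUm, function(cpt) {
      h <- base
      h["ONL+IS"] <- cpt / 2 - sum(base[c(1:4, 6)])
      h
    }))
  }
  allEqual <- computeSQF(mkSet(rep(210, 6)))
  expect_equal(allEqual@cptSdPercent, 0)
  expect_identical(sqf(allEqual), 1L)

  jumpy <- computeSQF(mkSet(c(200, 200, 200, 200, 200, 260)))
  expect_equal(jumpy@cptValuesUm, c(200, 200, 200, 200, 200, 260))
  expect_equal(jumpy@cptSdPercent, 100 * sd(c(rep(200, 5), 260)) / 210,
               tolerance = 1e-12)
  expect_gt(jumpy@cptSdPercent, 10)
  expect_identical(sqf(jumpy), 0L)

  steady <- computeSQF(mkSet(c(200, 202, 198, 201, 199, 200)))
  expect_lt(steady@cptSdPercent, 1)
  expect_identical(sqf(steady), 1L)
})

test_that("quality gate needs SQF = 1 and signal strength above 6", {
  ssOK <- uniformScanSet(signalStrength = 7L)
  expect_true(gateScanSet(ssOK)$accept)
  ss6 <- uniformScanSet(signalStrength = 6L)
  g6 <- gateScanSet(ss6)
  expect_false(g6$accept)
  expect_match(g6$reasons, "signal strength", all = FALSE)
  # SQF = 0 rejects regardless of signal
  base <- c("RNFL" = 10, "GCL+IPL" = 15, "INL" = 8, "OPL" = 8,
            "ONL+IS" = 45, "OS" = 14, "RPE" = 10)
  hh <- replicate(6, base, simplify = FALSE)
  hh[[6]]["ONL+IS"] <- 75
  bad <- uniformScanSet(nRows = 160L, perScanHeights = hh,
                        signalStrength = 10L)
  gBad <- gateScanSet(bad)
  expect_false(gBad$accept)
  expect_match(gBad$reasons, "SQF", all = FALSE)
})
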