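test_that("phase alignment rotates the energy-weighted mean phase to zero", {
  set.seed(2)
  base <- complex(real = rnorm(40), imaginary = rnorm(40) / 10) + 2
  pl <- matrix(base, 8, 5)
  al <- phaseAlign(pl * exp(1.1i))
  al0 <- phaseAlign(pl)
  expect_equal(al$real, al0$real, tolerance = 1e-12)
  expect_equal(Arg(sum(Mod(al$aligned) * al$aligned)), 0, tolerance = 1e-9)
})

test_that("Gaussian smoothing has the stated width and conserves the sum", {
  m <- matrix(0, 101, 101)
  m[51, 51] <- 1
  img <- new("ReconImage", values = m, fovMm = 101, pixelPitchMm = 1,
             method = "inverse_radon", provenance = list())
  expect_identical(gridValues(smoothImage(img, 0)), m)
  sm <- smoothImage(img, 6)
  expect_equal(sum(gridValues(sm)), 1, tolerance = 1e-6)
  pr <- centralProfile(sm, "x")
  v <- pr$values / max(pr$values)
  # interpolated half-maximum crossings
  left <- approx(v[46:51], pr$positions[46:51], xout = 0.5)$y
  right <- approx(rev(v[51:56]), rev(pr$positions[51:56]), xout = 0.5)$y
  expect_equal(right - left, 6, tolerance = 0.5)
})

test_that("filtered back-projection localizes and is linear", {
  sp <- testSpion()
  cfg <- tinyConfig(fovMm = 60, bins = 48, proj = 16)
  ph <- makePointSource(20, 6, pixelPitch = 0.75, extentMm = 60)
  sg <- preprocessSinogram(binToSinogram(simulateImage(ph, cfg, sp)))
  im <- inverseRadonRecon(sg, gridN = 80)
  v <- gridValues(im)
  pk <- which(v == max(v), arr.ind = TRUE)
  expect_lte(max(abs(pk - c(40.5, 40.5))), 1.5)     # within a pixel of isocenter
  # linearity: scaling the sinogram scales the image
  sg2 <- sg
  sg2@data <- sg2@data * 3.7
  im2 <- inverseRadonRecon(sg2, gridN = 80)
  expect_equal(gridValues(im2), 3.7 * v, tolerance = 1e-10)
  expect_error(inverseRadonRecon(sg, harmonic = 12), "not present")
})

test_that("two tubes 9 mm apart reconstruct at the right center distance", {
  sp <- testSpion()
  cfg <- resolutionConfig()
  ph <- makeLinePair(9, pixelPitch = 0.5, extentMm = 74)
  sg <- preprocessSinogram(binToSinogram(simulateImage(ph, cfg, sp)))
  im <- inverseRadonRecon(sg)
  cm <- contrastMetric(centralProfile(im)$values, centralProfile(im)$positions)
  expect_equal(diff(cm$peakPositions), 9 + 2.5, tolerance = 1.2 * pitchMm(im))
  expect_gt(cm$C, 0.5)
})

test_that("reconstructions superpose (linearity on sinogram pairs)", {
  sp <- testSpion()
  cfg <- tinyConfig(fovMm = 60, bins = 24, proj = 8)
  sgA <- binToSinogram(simulateImage(threePixelPhantom(), cfg, sp))
  phB <- makePointSource(20, 4, pixelPitch = 1, extentMm = 50, centerMm = c(-8, 5))
  sgB <- binToSinogram(simulateImage(phB, cfg, sp))
  sgSum <- sgA
  sgSum@data <- sgA@data + sgB@data
  # phase alignment is the only nonlinear step; bypass it by reconstructing
  # each plane with the same fixed global phase (zero, as these are
  # simulated with a common phase convention)
  A <- forwardModelForSinogram(sgA, kernelStdMm = 2, gridN = 30)
  rec <- function(sg) gridValues(iterativeRecon(Re(sg@data[, , "h3"]), A, nIter = 10))
  expect_equal(rec(sgSum), rec(sgA) + rec(sgB), tolerance = 1e-8)
  fb <- function(sg) gridValues(inverseRadonRecon(sg, smoothingFwhm = 0, gridN = 40))
  # global phases of the three planes are equal, so FBP is linear here too
  expect_equal(fb(sgSum), fb(sgA) + fb(sgB), tolerance = 1e-6)
})

test_that("forward-model rows have the stated geometry", {
  cfg <- scannerConfig(fovMm = 120, readoutsPerProjection = 16,
                       projectionsPerImage = 8)
  # band support: angle 0, shift 0 -> horizontal band of ~ +/- 4 sigma
  SM <- buildForwardModel(0, 0, cfg, kernelStdMm = 7, gridN = 48)
  row <- matrix(as.numeric(SM@A[1, ]), 48, 48)
  yc <- (seq_len(48) - 24.5) * SM@pixelPitchMm
  nz <- which(colSums(row) > 0)
  expect_true(all(abs(yc[nz]) <= 28 + SM@pixelPitchMm))
  expect_true(all(abs(yc[-nz]) > 28 - SM@pixelPitchMm))
  # opposite gantry half-turn with opposite shift gives the same line
  r1 <- buildForwardModel(30, 11, cfg, 7, 32)@A
  r2 <- buildForwardModel(210, -11, cfg, 7, 32)@A
  expect_lt(max(abs(r1 - r2)), 1e-12)
  # near-delta kernel approaches the ideal line integral
  SMd <- buildForwardModel(0, 0, cfg, kernelStdMm = SM@pixelPitchMm / 10,
                           gridN = 49)
  rowd <- matrix(as.numeric(SMd@A[1, ]), 49, 49)
  ideal <- matrix(0, 49, 49); ideal[, 25] <- SMd@pixelPitchMm
  expect_lt(max(abs(rowd - ideal)) / max(ideal), 0.02)
  expect_error(buildForwardModel(0, 0, cfg, kernelStdMm = 0), "> 0")
})

test_that("row sums are uniform for lines whose kernel fits in the grid", {
  cfg <- scannerConfig(fovMm = 120, readoutsPerProjection = 16,
                       projectionsPerImage = 8)
  # rows whose chord through the square grid is the full 120 mm and whose
  # Gaussian band lies inside: the line-integral normalization is uniform
  angles <- rep(c(0, 90), each = 9)
  shifts <- rep(seq(-20, 20, length.out = 9) * 1.13, 2)
  SM <- buildForwardModel(angles, shifts, cfg, kernelStdMm = 4, gridN = 48)
  rs <- Matrix::rowSums(SM@A)
  expect_lt((max(rs) - min(rs)) / mean(rs), 0.01)
  expect_true(all(SM@A@x >= 0))
})

test_that("truncated PCG solves the forward model", {
  cfg <- tinyConfig(fovMm = 64, bins = 32, proj = 24)
  na <- 24; ns <- 32
  angles <- rep(seq(0, 180 - 180 / na, length.out = na), each = ns)
  shifts <- rep(seq(-31, 31, length.out = ns) * 1.13, times = na)
  SM <- buildForwardModel(angles, shifts, cfg, kernelStdMm = 0.8, gridN = 16)
  A <- as.matrix(SM@A)
  xtrue <- numeric(256)
  xtrue[c(50, 120, 200)] <- c(1, 2, 1.5)
  b <- as.numeric(A %*% xtrue)
  # nIter = 0 returns the zero image
  expect_true(all(gridValues(iterativeRecon(b, SM, nIter = 0)) == 0))
  expect_error(iterativeRecon(b[-1], SM), "match")
  # 15 fixed iterations: forward-consistency oracle
  it15 <- iterativeRecon(b, SM, nIter = 15)
  v <- as.vector(gridValues(it15))
  top <- sort(order(v, decreasing = TRUE)[1:3])
  expect_identical(top, c(50L, 120L, 200L))
  expect_lt(max(abs(v[top] - c(1, 2, 1.5)) / c(1, 2, 1.5)), 0.05)
  # normal-equation residuals decrease on noiseless data
  expect_true(all(diff(it15@provenance$residuals) < 0))
  # dense least-squares oracle (independent route): equal residuals
  xp <- MASS::ginv(A) %*% b
  xc <- as.vector(gridValues(iterativeRecon(b, SM, nIter = 300)))
  nb <- sqrt(sum(b^2))
  gap <- abs(sqrt(sum((b - A %*% xc)^2)) - sqrt(sum((b - A %*% xp)^2))) / nb
  expect_lt(gap, 1e-3)
})

test_that("recon images round-trip through CSV + JSON", {
  m <- matrix(rnorm(64), 8, 8)
  img <- new("ReconImage", values = m, fovMm = 40, pixelPitchMm = 5,
             method = "iterative", provenance = list(nIter = 15))
  f <- tempfile()
  writeReconImage(img, f)
  img2 <- readReconImage(f)
  expect_equal(gridValues(img2), m, tolerance = 1e-12)
  expect_equal(fovMm(img2), 40)
  expect_identical(img2@method, "iterative")
  # float TIFF export: values recover through the sidecar offset/scale
  ft <- tempfile(fileext = ".tif")
  writeGridTiff(img, ft)
  meta <- jsonlite::read_json(paste0(ft, ".json"), simplifyVector = TRUE)
  back <- meta$offset + meta$scale * tiff::readTIFF(ft)
  expect_equal(back, m, tolerance = 1e-6)
})
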