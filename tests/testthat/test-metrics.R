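test_that("contrast statistic matches hand arithmetic", {
  expect_equal(contrastMetric(c(0, 1, 0, 1, 0))$C, 1)
  expect_equal(contrastMetric(c(0, 1, 1, 1, 0))$C, 0)       # flat top
  cm <- contrastMetric(c(0, 1, 0.45, 0.8, 0))
  expect_equal(cm$C, 1 - 0.45 / 0.9)
  expect_identical(c(cm$sMaxLeft, cm$sMaxRight), c(1, 0.8))
  expect_error(contrastMetric(c(0, 0.2, 0.6, 1, 1.2)), "local maxima")
  expect_error(contrastMetric(c(0, 1, 0)), "short")
})

test_that("contrast is invariant to positive rescaling and ignores sidelobes", {
  prof <- c(0.05, 0.3, 0.1, 0.2, 0.9, 1.0, 0.6, 0.35, 0.55, 0.95, 0.8, 0.25,
            0.3, 0.08)
  c1 <- contrastMetric(prof)
  c2 <- contrastMetric(prof * 37.2)
  expect_equal(c1$C, c2$C, tolerance = 1e-12)
  expect_identical(c1$peakPositions, c2$peakPositions)
  # prominence-based selection: the two tube peaks win over ringing bumps
  x <- seq(-20, 20, by = 0.5)
  tubes <- exp(-(x - 5)^2 / 4) + exp(-(x + 5)^2 / 4)
  ringing <- 0.35 * exp(-(x - 13)^2 / 2) + 0.35 * exp(-(x + 13)^2 / 2)
  cm <- contrastMetric(tubes + ringing, x)
  expect_equal(cm$peakPositions, c(-5, 5), tolerance = 0.5)
})

test_that("resolution from a series returns the smallest resolved separation", {
  mkimg <- function(C) {
    # two unit peaks at x = 12 and 21 with a controlled valley between them
    x <- seq_len(32)
    prof <- numeric(32)
    prof[x < 12] <- pmax(0, (x[x < 12] - 6) / 6)
    prof[x > 21] <- pmax(0, (27 - x[x > 21]) / 6)
    mid <- x >= 12 & x <= 21
    prof[mid] <- 1 - C * sin(pi * (x[mid] - 12) / 9)^2
    new("ReconImage", values = matrix(rep(prof, 32), 32, 32), fovMm = 32,
        pixelPitchMm = 1, method = "inverse_radon", provenance = list())
  }
  imgs <- lapply(c(0.2, 0.35, 0.62, 0.8, 0.9), mkimg)
  res <- resolutionFromSeries(imgs, 5:9)
  expect_equal(res$resolvedMm, 7)
  expect_true(res$resolved)
  res2 <- resolutionFromSeries(imgs[3:5], 7:9)
  expect_equal(res2$resolvedMm, 7)   # all resolved: smallest separation
  res3 <- resolutionFromSeries(imgs[1:2], 5:6)
  expect_true(is.na(res3$resolvedMm))
  expect_false(res3$resolved)
})

test_that("detection limit follows the fitted line against k sigma", {
  dl <- detectionLimit(c(1, 2, 3, 4), 2 * c(1, 2, 3, 4), 10)
  expect_equal(dl$lod1SigmaG, 5)
  expect_equal(dl$lod5SigmaG, 25)
  expect_equal(dl$rSquared, 1)
  # intercept effect: lod5 - 5 lod1 = 4 b / a, so a positive baseline pushes
  # the 5-sigma crossing beyond 5x the 1-sigma one (and vice versa)
  dlb <- detectionLimit(c(1, 2, 3, 4), 3 + 2 * c(1, 2, 3, 4), 10)
  expect_equal(dlb$lod5SigmaG - 5 * dlb$lod1SigmaG, 4 * 3 / 2, tolerance = 1e-9)
  dlneg <- detectionLimit(c(1, 2, 3, 4), -3 + 2 * c(1, 2, 3, 4), 10)
  expect_lt(dlneg$lod5SigmaG, 5 * dlneg$lod1SigmaG)
  expect_gte(dlb$lod5SigmaG, dlb$lod1SigmaG)
  expect_error(detectionLimit(1:4, rep(1, 4), 1), "slope")
  expect_error(detectionLimit(1:4, 1:4, 0), "noiseSigma")
})

test_that("LOD scales inversely with the regression slope", {
  m <- c(1, 2, 4, 8)
  d1 <- detectionLimit(m, 2 * m, 4)
  d2 <- detectionLimit(m, 1 * m, 4)      # halved sensitivity
  expect_equal(d2$lod5SigmaG, 2 * d1$lod5SigmaG, tolerance = 1e-12)
})

test_that("FOV calibration is the pixel-extent proportion", {
  img <- new("ReconImage", values = matrix(0, 132, 132), fovMm = 132,
             pixelPitchMm = 1, method = "inverse_radon", provenance = list())
  expect_equal(fovCalibration(img, 136, 99), 136 * 132 / 99)
  expect_equal(fovCalibration(img, 150, 132), 150)
  expect_error(fovCalibration(img, 136, 1), "2 pixels")
})

test_that("feedthrough attenuation reproduces the gradiometer arithmetic", {
  expect_equal(feedthroughAttenuation(10, 1, 10, 1), 40)
  expect_equal(feedthroughAttenuation(2, 2, 5, 5), 0)
  # inverse check of the published 83 dBc point: currents 16.4/1.67 A with
  # the voltage ratio that closes the identity
  vRatio <- 10^(83 / 20) * (1.67 / 16.4)
  expect_equal(feedthroughAttenuation(vRatio, 1, 16.4, 1.67), 83,
               tolerance = 1e-9)
  expect_error(feedthroughAttenuation(-1, 1, 1, 1), "positive")
})

test_that("image SNR is peak over in-FOV noise standard deviation", {
  set.seed(9)
  noise <- matrix(rnorm(40^2), 40, 40)
  nimg <- new("ReconImage", values = noise, fovMm = 40, pixelPitchMm = 1,
              method = "inverse_radon", provenance = list())
  xc <- (seq_len(40) - 20.5)
  s <- sd(noise[outer(xc^2, xc^2, "+") <= 400])
  sig <- matrix(0, 40, 40); sig[20, 20] <- 5 * s
  simg <- new("ReconImage", values = sig, fovMm = 40, pixelPitchMm = 1,
              method = "inverse_radon", provenance = list())
  expect_equal(imageSNR(simg, nimg), 5, tolerance = 1e-12)
  # common rescaling leaves SNR unchanged
  simg2 <- simg; simg2@values <- simg2@values * 3
  nimg2 <- nimg; nimg2@values <- nimg2@values * 3
  expect_equal(imageSNR(simg2, nimg2), 5, tolerance = 1e-12)
  zimg <- nimg; zimg@values <- matrix(0, 40, 40)
  expect_error(imageSNR(simg, zimg), "zero noise")
})

test_that("subpixel extent measurement recovers a known peak distance", {
  n <- 101
  yc <- (seq_len(n) - 51)
  prof <- exp(-(yc - 34.3)^2 / 8) + exp(-(yc + 34.3)^2 / 8)
  img <- new("ReconImage", values = matrix(rep(prof, n), n, n, byrow = TRUE),
             fovMm = n, pixelPitchMm = 1, method = "inverse_radon",
             provenance = list())
  expect_equal(measureExtentPx(img, axis = "y"), 68.6, tolerance = 0.1)
})
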