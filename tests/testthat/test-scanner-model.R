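test_that("langevin matches its series oracle and limiting values", {
  expect_identical(langevin(0), 0)
  expect_lt(abs(langevin(1e6) - 1), 1e-5)
  # independent oracle: truncated odd series xi/3 - xi^3/45 + 2 xi^5/945
  xi <- 0.3
  series <- xi / 3 - xi^3 / 45 + 2 * xi^5 / 945
  expect_equal(langevin(xi), series, tolerance = 1e-5)
  expect_error(langevin(Inf), "finite")
  expect_error(langevin(NaN), "finite")
})

test_that("langevin is odd, strictly increasing, and bounded in (-1, 1)", {
  xi <- seq(-50, 50, length.out = 2001)
  L <- langevin(xi)
  expect_equal(L, -rev(L), tolerance = 1e-12)
  expect_true(all(diff(L) > 0))
  expect_true(all(abs(L) < 1))
})

test_that("harmonic response has the symmetries of the Langevin model", {
  sp <- testSpion()
  h0 <- harmonicResponse(0, 5.8, sp)
  # even harmonics vanish at zero offset (odd symmetry of L)
  expect_lt(Mod(h0[, "h2"]), 1e-10 * Mod(h0[, "h3"]))
  expect_lt(Mod(h0[, "h4"]), 1e-10 * Mod(h0[, "h3"]))
  # deep saturation kills every harmonic
  sat <- harmonicResponse(10 * (5.8 + 1000 / sp@beta * 1000), 5.8, sp)
  expect_lt(max(Mod(sat)), 1e-6 * Mod(h0[, "h3"]))
  # |h_n| is even in the offset for every n
  hp <- harmonicResponse(c(4.2, -4.2), 5.8, sp)
  expect_equal(Mod(hp[1, ]), Mod(hp[2, ]), tolerance = 1e-12)
  # linear in signalScale
  sp2 <- spionModel(signalScale = 3.5, beta = sp@beta)
  expect_equal(harmonicResponse(2.1, 5.8, sp2),
               3.5 * harmonicResponse(2.1, 5.8, sp), tolerance = 1e-12)
  expect_error(harmonicResponse(0, 0, sp), "positive")
})

test_that("beta calibration reproduces the 6 mT third-harmonic kernel", {
  sp <- testSpion()
  fw <- measureKernelFwhm(sp@beta, 5.8)
  expect_gte(fw, 5.94)
  expect_lte(fw, 6.06)
  # joint rescaling of target and drive scales beta exactly inversely
  b12 <- calibrateBeta(12, 2 * 5.8)
  expect_equal(b12 / sp@beta, 0.5, tolerance = 1e-4)
  # at fixed drive the scaling is only approximately inverse
  b12f <- calibrateBeta(12, 5.8)
  expect_lt(b12f, sp@beta)
  expect_error(calibrateBeta(-1), "> 0")
  expect_error(calibrateBeta(6, 5.8, interval = c(1e5, 1e6)), "bracket")
})

test_that("FFL offset field follows the line geometry", {
  cfg <- scannerConfig()
  expect_equal(fflOffsetField(c(0, 0), 37, 0, cfg), 0)
  # 10 mm perpendicular at 1.13 T/m is 11.3 mT (hand arithmetic)
  expect_equal(fflOffsetField(c(0, 10), 0, 0, cfg), 11.3)
  # a shift of -G d cancels the gradient offset
  d <- fflOffsetField(c(7, -3), 55, 0, cfg)
  expect_equal(fflOffsetField(c(7, -3), 55, -d, cfg), 0, tolerance = 1e-12)
})

test_that("FFL offset field is invariant along the line and under joint rotation", {
  cfg <- scannerConfig()
  th <- 33 * pi / 180
  p <- c(4, -9)
  # translate along the line direction (cos th, sin th)
  p2 <- p + 25 * c(cos(th), sin(th))
  expect_equal(fflOffsetField(p, 33, 5, cfg), fflOffsetField(p2, 33, 5, cfg),
               tolerance = 1e-9)
  # rotate the point and the gantry by the same angle
  a <- 48 * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  expect_equal(fflOffsetField(p, 33, 5, cfg),
               fflOffsetField(as.numeric(R %*% p), 33 + 48, 5, cfg),
               tolerance = 1e-9)
})

test_that("scanner config validity enforces integer samples per period", {
  expect_error(scannerConfig(driveFrequency = 26000), "integer")
  expect_error(scannerConfig(gradientInplane = -1), "positive")
  cfg <- scannerConfig()
  expect_equal(fovMm(cfg), 181)
  expect_equal(cfg@shiftFrequency, 2.7)
})

test_that("config YAML round-trips and the packaged default matches", {
  cfg <- scannerConfig(fovMm = 74)
  f <- tempfile(fileext = ".yaml")
  writeScannerConfig(cfg, f)
  cfg2 <- readScannerConfig(f)
  for (nm in slotNames(cfg))
    expect_equal(slot(cfg2, nm), slot(cfg, nm), tolerance = 1e-12)
  pkgd <- readScannerConfig(system.file("extdata", "default-config.yaml",
                                        package = "fflmpi"))
  dflt <- scannerConfig()
  for (nm in slotNames(dflt))
    expect_equal(slot(pkgd, nm), slot(dflt, nm), tolerance = 1e-9)
})
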