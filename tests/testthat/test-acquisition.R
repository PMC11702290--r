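test_that("acquisition timing reproduces the console numbers", {
  tm <- makeTiming(scannerConfig())
  expect_equal(signif(tm$readoutDuration, 3), 1.33e-3)
  expect_identical(tm$samplesPerReadout, 1330L)       # 35 periods x 38 samples
  expect_equal(tm$imageDuration, 5)
  expect_equal(tm$projectionDuration, 5 / 27)
  expect_equal(tm$impliedShiftFrequency, 2.7)
  expect_gte(tm$deadTimePerProjection, 0)
})

test_that("shift waveform has triangle geometry and RMS peak/sqrt(3)", {
  cfg <- scannerConfig()
  peak <- cfg@shiftFieldPeak
  Tp <- 1 / cfg@shiftFrequency
  expect_equal(shiftWaveform(0, cfg), -peak)          # corner at t = 0
  expect_equal(shiftWaveform(Tp / 2, cfg), peak)
  expect_equal(shiftWaveform(0.25 * Tp + Tp / 4, cfg), peak)  # quarter period past zero crossing
  tt <- seq(0, Tp, length.out = 4e5 + 1)[-1]
  expect_equal(sqrt(mean(shiftWaveform(tt, cfg)^2)), peak / sqrt(3),
               tolerance = 1e-6)
  # rounding keeps continuity and pulls the extremum inside the ideal peak
  wr <- shiftWaveform(tt, cfg, roundingFraction = 0.05)
  expect_lt(max(wr), peak)
  expect_lt(max(abs(diff(wr))), 2 * max(abs(diff(shiftWaveform(tt, cfg)))))
  expect_error(shiftWaveform(0, cfg, roundingFraction = 0.6), "roundingFraction")
})

test_that("time-domain read-out agrees with the harmonic response kernel", {
  sp <- testSpion()
  cfg <- scannerConfig()
  pts <- rbind(c(0, 0), c(5, -3), c(-8, 12))
  mass <- c(1e-6, 2e-6, 5e-7)
  td <- simulateReadoutTimedomain(pts, mass, 33, 7.5, cfg, sp)
  hr <- harmonicResponse(fflOffsetField(pts, 33, 7.5, cfg),
                         cfg@driveAmplitude, sp)
  direct <- colSums(hr * mass)
  expect_lt(max(Mod(td - direct)) / max(Mod(direct)), 1e-6)
  # single point at the isocenter, zero shift: even harmonics vanish
  iso <- simulateReadoutTimedomain(c(0, 0), 1e-6, 70, 0, cfg, sp)
  expect_lt(Mod(iso["h2"]), 1e-10 * Mod(iso["h3"]))
  expect_lt(Mod(iso["h4"]), 1e-10 * Mod(iso["h3"]))
})

test_that("fast kernel mode matches the time-domain oracle within 1%", {
  sp <- testSpion()
  cfg <- tinyConfig()
  ph <- threePixelPhantom()
  ro <- simulateImage(ph, cfg, sp)
  pp <- phantomPoints(ph)
  for (i in c(1L, 57L, 200L, nrow(ro@harmonics))) {
    td <- simulateReadoutTimedomain(pp$xy, pp$massG, ro@angleDeg[i],
                                    ro@shiftMt[i], cfg, sp)
    expect_lt(max(Mod(ro@harmonics[i, ] - td)) / max(Mod(td)), 0.01)
  }
})

test_that("read-out signal is linear in phantom concentration", {
  sp <- testSpion()
  cfg <- tinyConfig()
  ph <- threePixelPhantom()
  ph2 <- ph
  ph2@grid <- 2 * ph2@grid
  r1 <- simulateImage(ph, cfg, sp)
  r2 <- simulateImage(ph2, cfg, sp)
  expect_equal(r2@harmonics, 2 * r1@harmonics, tolerance = 1e-12)
})

test_that("a centered point source peaks at zero shift in every projection", {
  sp <- testSpion()
  cfg <- tinyConfig()
  ph <- makePointSource(20, 6, pixelPitch = 1, extentMm = 40, )
  ro <- simulateImage(ph, cfg, sp)
  tm <- makeTiming(cfg)
  proj <- floor(ro@timestamp / tm$projectionDuration)
  binW <- 2 * cfg@shiftFieldPeak / cfg@readoutsPerProjection
  for (k in unique(proj)) {
    sel <- proj == k
    pk <- ro@shiftMt[sel][which.max(Mod(ro@harmonics[sel, "h3"]))]
    expect_lt(abs(pk), 1.5 * binW)
  }
})

test_that("seeded acquisitions are reproducible and seeds only move the noise", {
  sp <- testSpion()
  cfg <- tinyConfig()
  ph <- threePixelPhantom()
  a <- simulateImage(ph, cfg, sp, noiseSigma = 1e-9, spikeRate = 0.02, seed = 11)
  b <- simulateImage(ph, cfg, sp, noiseSigma = 1e-9, spikeRate = 0.02, seed = 11)
  expect_identical(a@harmonics, b@harmonics)
  expect_identical(a@spiked, b@spiked)
  c <- simulateImage(ph, cfg, sp, noiseSigma = 1e-9, seed = 12)
  expect_false(identical(a@harmonics, c@harmonics))
  clean <- simulateImage(ph, cfg, sp)
  expect_lt(max(Mod(c@harmonics - clean@harmonics)), 1e-9 * 10)
})

test_that("binning is the identity on synthetic uniform read-outs and averages duplicates", {
  cfg <- tinyConfig(bins = 8, proj = 2)
  nb <- 8L
  centers <- (seq_len(nb) - 0.5) / nb * 2 * cfg@shiftFieldPeak - cfg@shiftFieldPeak
  tm <- makeTiming(cfg)
  H <- matrix(complex(real = rnorm(16 * 8), imaginary = rnorm(16 * 8)), 16, 8)
  colnames(H) <- paste0("h", 2:9)
  ro <- new("ReadoutSet", harmonics = H,
            angleDeg = rep(c(10, 40), each = nb),
            shiftMt = rep(centers, 2),
            timestamp = rep(c(0.5, 1.5) * tm$projectionDuration, each = nb),
            spiked = logical(16), config = cfg, seed = NA_real_)
  sg <- binToSinogram(ro)
  expect_equal(sg@data[, 1, "h3"], H[1:8, "h3"], tolerance = 1e-12)
  expect_equal(sg@data[, 2, "h5"], H[9:16, "h5"], tolerance = 1e-12)
  expect_false(any(sg@interpolated))
  expect_equal(sg@angleDeg, c(10, 40))
  # two read-outs in one bin are complex-averaged; the vacated bin is
  # interpolated and flagged
  ro2 <- ro
  ro2@shiftMt[2] <- centers[1]
  sg2 <- binToSinogram(ro2)
  expect_equal(sg2@data[1, 1, "h3"], (H[1, "h3"] + H[2, "h3"]) / 2,
               tolerance = 1e-12)
  expect_true(sg2@interpolated[2, 1])
})

test_that("corner dwell of the rounded triangle leaves edge bins interpolated", {
  sp <- testSpion()
  cfg <- tinyConfig()
  ph <- makePointSource(20, 6, pixelPitch = 1, extentMm = 40)
  ro <- simulateImage(ph, cfg, sp, roundingFraction = 0.05)
  # occupancy oracle: no read-out mean shift reaches the outermost bins
  binW <- 2 * cfg@shiftFieldPeak / cfg@readoutsPerProjection
  expect_lt(max(abs(ro@shiftMt)), cfg@shiftFieldPeak - binW)
  sg <- binToSinogram(ro)
  expect_true(all(sg@interpolated[1, ]))
  expect_true(all(sg@interpolated[nrow(sg@interpolated), ]))
})

test_that("projection mass is conserved across angles for an interior phantom", {
  sp <- testSpion()
  cfg <- tinyConfig(fovMm = 80, bins = 40)
  ph <- makePointSource(200, 2, pixelPitch = 1, extentMm = 50, depthMm = 5)
  sg <- binToSinogram(simulateImage(ph, cfg, sp))
  m0 <- colSums(Mod(sg@data[, , "h3"]))
  expect_lt((max(m0) - min(m0)) / mean(m0), 0.02)
  # centered disc: the 3rd-harmonic profile is identical across projections
  pl <- Mod(sg@data[, , "h3"])
  ref <- rowMeans(pl)
  rms <- apply(pl, 2, function(col) sqrt(mean((col - ref)^2)) / max(ref))
  expect_lt(max(rms), 0.01)
})

test_that("sinogram JSON container round-trips", {
  sp <- testSpion()
  cfg <- tinyConfig(bins = 12, proj = 4)
  ph <- threePixelPhantom()
  sg <- binToSinogram(simulateImage(ph, cfg, sp, noiseSigma = 1e-9, seed = 3))
  f <- tempfile(fileext = ".json")
  writeSinogram(sg, f)
  sg2 <- readSinogram(f)
  expect_equal(sg2@data, sg@data, tolerance = 1e-12)
  expect_equal(sg2@shiftMt, sg@shiftMt, tolerance = 1e-12)
  expect_equal(sg2@angleDeg, sg@angleDeg, tolerance = 1e-12)
  expect_identical(sg2@interpolated, sg@interpolated)
  expect_equal(fovMm(sg2@provenance$config), fovMm(cfg))
})
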