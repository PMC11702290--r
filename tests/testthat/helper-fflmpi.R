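# shared fixtures: a memoized calibrated tracer and small scanner configs

.fixtures <- new.env(parent = emptyenv())

testSpion <- function() {
  if (is.null(.fixtures$spion)) .fixtures$spion <- spionModel()
  .fixtures$spion
}

# small but valid scanner geometry for fast pipeline tests: the gantry
# speed is chosen so the read-outs fill ~95% of each projection slot and
# the shift ramp is covered bin by bin, as in the full-size acquisition
tinyConfig <- function(fovMm = 60, bins = 32, proj = 12, ...) {
  roDur <- 35 / (1e6 / 38)
  imageDur <- proj * bins * roDur / 0.95
  scannerConfig(fovMm = fovMm, readoutsPerProjection = bins,
                projectionsPerImage = proj,
                gantryRpm = (180 / 360) * 60 / imageDur, ...)
}

# phantom with three isolated pixels at known positions (kernel-mode oracle)
threePixelPhantom <- function(pitch = 2, n = 21, depth = 2) {
  g <- matrix(0, n, n)
  g[11, 11] <- 1
  g[14, 9] <- 2
  g[6, 16] <- 0.5
  new("PhantomImage", grid = g, pixelPitch = pitch, depth = depth,
      origin = c((n + 1) / 2, (n + 1) / 2))
}

# grid coordinates of the nonzero pixels of a phantom, with masses in g
phantomPoints <- function(ph) {
  nz <- which(ph@grid > 0, arr.ind = TRUE)
  list(xy = cbind((nz[, 1] - ph@origin[1]) * ph@pixelPitch,
                  (nz[, 2] - ph@origin[2]) * ph@pixelPitch),
       massG = ph@grid[nz] * ph@pixelPitch^2 * ph@depth * 1e-6)
}

# ground truth for despiker tests: sinogram bins containing >= 1 spiked RO,
# using the same shift-bin / projection assignment as binToSinogram
.spikeBinTruth <- function(ro, cfg) {
  nb <- as.integer(cfg@readoutsPerProjection)
  np <- as.integer(cfg@projectionsPerImage)
  edges <- seq(-cfg@shiftFieldPeak, cfg@shiftFieldPeak, length.out = nb + 1)
  tm <- makeTiming(cfg)
  proj <- pmin(pmax(floor(ro@timestamp / tm$projectionDuration), 0), np - 1) + 1
  b <- pmin(pmax(findInterval(ro@shiftMt, edges, rightmost.closed = TRUE), 1), nb)
  truth <- matrix(FALSE, nb, np)
  truth[cbind(b[ro@spiked], proj[ro@spiked])] <- TRUE
  truth
}

# smooth extended emission phantom: broad Gaussian concentration profile,
# the regime where an additive transient exceeds the local signal level
# everywhere (the premise of the despiker recall property)
gaussBlobPhantom <- function(extentMm, pitch, sigmaMm, center = c(0, 0)) {
  n <- as.integer(ceiling(extentMm / pitch))
  xc <- (seq_len(n) - (n + 1) / 2) * pitch
  g <- exp(-outer((xc - center[1])^2, (xc - center[2])^2, "+") /
             (2 * sigmaMm^2))
  new("PhantomImage", grid = g, pixelPitch = pitch, depth = 5,
      origin = c((n + 1) / 2, (n + 1) / 2))
}
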