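# One-image acquisition simulation: gantry sweep, triangular shift
# waveform, read-out segmentation, harmonic signal generation, noise and
# spike injection, and console-style binning into sinograms.

#' Derive the acquisition timing of one image
#'
#' Read-outs are contiguous blocks of `periodsPerReadout` drive periods;
#' the slack between `readoutsPerProjection` read-outs and the projection
#' slot (image duration / projections) is dead time, split evenly across
#' the projection boundaries. Also reports the shift frequency implied by
#' 2 projections per triangle period.
#'
#' @param config a [ScannerConfig-class].
#' @return list with `readoutDuration` (s), `samplesPerPeriod`,
#'   `samplesPerReadout`, `readoutsPerImage`, `projectionDuration` (s),
#'   `imageDuration` (s), `deadTimePerProjection` (s),
#'   `impliedShiftFrequency` (Hz).
#' @examples
#' tm <- makeTiming(scannerConfig())
#' tm$readoutDuration  # 1.33 ms
#' tm$imageDuration    # 5 s
#' @export
makeTiming <- function(config) {
  stopifnot(is(config, "ScannerConfig"))
  spp <- config@sampleRate / config@driveFrequency
  if (abs(spp - round(spp)) > 1e-6)
    stop("makeTiming: non-integer samples per drive period")
  spp <- round(spp)
  roDur <- config@periodsPerReadout / config@driveFrequency
  imageDur <- (config@imageSweepDegrees / 360) * 60 / config@gantryRpm
  projDur <- imageDur / config@projectionsPerImage
  dead <- projDur - config@readoutsPerProjection * roDur
  if (dead < -1e-12)
    stop("makeTiming: read-outs do not fit in the projection slot")
  list(
    readoutDuration = roDur,
    samplesPerPeriod = spp,
    samplesPerReadout = as.integer(spp * config@periodsPerReadout),
    readoutsPerImage = as.integer(config@readoutsPerProjection * config@projectionsPerImage),
    projectionDuration = projDur,
    imageDuration = imageDur,
    deadTimePerProjection = max(dead, 0),
    impliedShiftFrequency = config@projectionsPerImage / (2 * imageDur)
  )
}

#' Rounded-triangle shift waveform
#'
#' Periodic triangle of amplitude `shiftFieldPeak` at `shiftFrequency`,
#' starting at its negative corner at t = 0 (so each projection slot is one
#' monotone half-period). With `roundingFraction` > 0 the corners are
#' blended with a cosine arc over that fraction of the period, continuous in
#' value and slope; the blended extremum sits slightly inside the ideal peak
#' (by peak * 2 * pi * roundingFraction * (1 - 2/pi)), the corner-dwell
#' distortion real shift amplifiers show. `roundingFraction = 0` is the
#' exact triangle.
#'
#' @param t time(s), s.
#' @param config a [ScannerConfig-class].
#' @param roundingFraction fraction of the period over which each corner is
#'   smoothed, in `[0, 0.5)`.
#' @return shift field(s), mT.
#' @export
shiftWaveform <- function(t, config, roundingFraction = 0) {
  stopifnot(is(config, "ScannerConfig"))
  if (roundingFraction < 0 || roundingFraction >= 0.5)
    stop("shiftWaveform: roundingFraction must be in [0, 0.5)")
  peak <- config@shiftFieldPeak
  Tp <- 1 / config@shiftFrequency
  phi <- (t / Tp) %% 1
  y <- ifelse(phi < 0.5, -peak + 4 * peak * phi, 3 * peak - 4 * peak * phi)
  if (roundingFraction > 0) {
    h <- roundingFraction * Tp / 2          # half-window, s
    hp <- h / Tp                            # in phase units
    s <- 4 * peak / Tp                      # triangle slope, mT/s
    c2 <- 2 * s * h / pi
    c0 <- peak - s * h
    # distance (phase units) to the nearest corner; corners at phi = 0, 0.5, 1
    dv <- pmin(phi, 1 - phi)                # valley corners (value -peak)
    dp <- abs(phi - 0.5)                    # peak corner (value +peak)
    inv <- dv < hp
    ipk <- dp < hp
    tau <- dv * Tp
    y[inv] <- -(c0 + c2 * cos(pi * tau[inv] / (2 * h)))
    tau <- dp * Tp
    y[ipk] <- c0 + c2 * cos(pi * tau[ipk] / (2 * h))
  }
  y
}

# linear interpolation of a complex kernel table at arbitrary offsets
.interpKernel <- function(offsets, offGrid, Ktab) {
  n <- length(offGrid)
  idx <- findInterval(offsets, offGrid)
  idx[idx < 1L] <- 1L
  idx[idx > n - 1L] <- n - 1L
  w <- (offsets - offGrid[idx]) / (offGrid[idx + 1L] - offGrid[idx])
  w <- pmin(pmax(w, 0), 1)
  list(idx = idx, w = w)
}

#' Simulate one image acquisition
#'
#' For each read-out the mean gantry angle and mean shift field come from
#' the timing model (continuous rotation, rounded-triangle shift). Each
#' harmonic amplitude is the sum over phantom pixels of pixel iron mass
#' times the tracer's [harmonicResponse()] at that pixel's
#' [fflOffsetField()]. The response is evaluated through a precomputed
#' offset-field kernel table with linear interpolation ("fast kernel
#' mode"); [simulateReadoutTimedomain()] is the brute-force oracle for it.
#'
#' Complex white Gaussian noise of per-component scale `noiseSigma` is
#' added to every harmonic of every read-out. With probability `spikeRate`
#' a read-out's 3rd harmonic receives an additive transient of amplitude
#' `spikeFactor` times the plane's RMS magnitude at a uniform random phase,
#' mimicking arcing in the shift system coupling into the receive chain
#' (an additive interferer, present also where the particle signal is
#' zero). Fully reproducible from `seed`.
#'
#' @param phantom a [PhantomImage-class]; an empty phantom yields
#'   noise-only read-outs.
#' @param config a [ScannerConfig-class].
#' @param spion a [SpionModel-class].
#' @param noiseSigma per-component Gaussian noise scale, signal units.
#' @param spikeRate per-read-out spike probability.
#' @param spikeFactor spike amplitude in units of the plane RMS magnitude.
#' @param seed integer seed; NULL leaves the RNG untouched (only valid
#'   when noiseSigma and spikeRate are both zero gives identical output).
#' @param nHarmonics highest harmonic simulated (default 9).
#' @param roundingFraction shift-corner rounding passed to [shiftWaveform()].
#' @param kernelStepMt offset step of the kernel lookup table, mT.
#' @return a [ReadoutSet-class].
#' @export
simulateImage <- function(phantom, config, spion, noiseSigma = 0,
                          spikeRate = 0, spikeFactor = 20, seed = NULL,
                          nHarmonics = 9, roundingFraction = 0.02,
                          kernelStepMt = 0.05) {
  stopifnot(is(phantom, "PhantomImage"), is(config, "ScannerConfig"),
            is(spion, "SpionModel"))
  tm <- makeTiming(config)
  nRO <- tm$readoutsPerImage
  nPerProj <- as.integer(config@readoutsPerProjection)
  if (fovMm(phantom) > fovMm(config) + phantom@pixelPitch)
    warning("phantom extent exceeds the configured field of view")

  # read-out mid-times, mean angles, mean shift fields
  p <- rep(seq_len(as.integer(config@projectionsPerImage)) - 1L, each = nPerProj)
  m <- rep(seq_len(nPerProj) - 1L, times = config@projectionsPerImage)
  t0 <- p * tm$projectionDuration + tm$deadTimePerProjection / 2 + m * tm$readoutDuration
  tmid <- t0 + tm$readoutDuration / 2
  degPerSec <- 6 * config@gantryRpm  # 360 * rpm / 60
  angles <- degPerSec * tmid
  # mean shift over the RO: average the waveform at the drive-period midpoints
  np <- as.integer(config@periodsPerReadout)
  pm <- ((seq_len(np) - 0.5) / config@driveFrequency)
  shifts <- vapply(t0, function(tt)
    mean(shiftWaveform(tt + pm, config, roundingFraction)), numeric(1))

  # particle signal via the kernel table
  nz <- which(phantom@grid > 0, arr.ind = TRUE)
  H <- matrix(0 + 0i, nRO, 8)
  colnames(H) <- paste0("h", 2:9)
  if (nrow(nz) > 0L) {
    px <- (nz[, 1L] - phantom@origin[1L]) * phantom@pixelPitch
    py <- (nz[, 2L] - phantom@origin[2L]) * phantom@pixelPitch
    massG <- phantom@grid[nz] * phantom@pixelPitch^2 * phantom@depth * 1e-6
    maxOff <- config@gradientInplane * max(sqrt(px^2 + py^2)) +
      config@shiftFieldPeak + 2 * kernelStepMt
    offGrid <- seq(-maxOff, maxOff, by = kernelStepMt)
    Ktab <- harmonicResponse(offGrid, config@driveAmplitude, spion,
                             nHarmonics = nHarmonics,
                             samplesPerPeriod = tm$samplesPerPeriod)
    if (ncol(Ktab) < 8)
      Ktab <- cbind(Ktab, matrix(0 + 0i, nrow(Ktab), 8 - ncol(Ktab)))
    th <- angles * pi / 180
    for (i in seq_len(nRO)) {
      d <- -px * sin(th[i]) + py * cos(th[i])
      off <- config@gradientInplane * d + shifts[i]
      iw <- .interpKernel(off, offGrid, Ktab)
      H[i, ] <- colSums(Ktab[iw$idx, , drop = FALSE] * ((1 - iw$w) * massG)) +
                colSums(Ktab[iw$idx + 1L, , drop = FALSE] * (iw$w * massG))
    }
  }

  spiked <- logical(nRO)
  if (noiseSigma > 0 || spikeRate > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
      }, add = TRUE)
      set.seed(as.integer(seed))
    }
    if (noiseSigma > 0) {
      H <- H + matrix(complex(real = rnorm(nRO * 8, sd = noiseSigma),
                              imaginary = rnorm(nRO * 8, sd = noiseSigma)),
                      nRO, 8)
    }
    if (spikeRate > 0) {
      spiked <- runif(nRO) < spikeRate
      if (any(spiked)) {
        level <- sqrt(mean(Mod(H[, "h3"])^2))
        if (level <= 0) level <- 1  # degenerate all-zero plane
        phase <- runif(sum(spiked), 0, 2 * pi)
        H[spiked, "h3"] <- H[spiked, "h3"] +
          spikeFactor * level * complex(modulus = 1, argument = phase)
      }
    }
  }

  new("ReadoutSet", harmonics = H, angleDeg = angles, shiftMt = shifts,
      timestamp = tmid, spiked = spiked, config = config,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Brute-force time-domain read-out simulation (oracle)
#'
#' Synthesizes the magnetization of a few point masses over a full
#' read-out at the digitizer rate, applies the per-sample difference
#' (Faraday induction) and a single FFT, and reads harmonic n at FFT bin
#' `periodsPerReadout * n`. Mathematically identical to
#' [harmonicResponse()] for a static offset; kept as the independent code
#' path that validates the fast kernel mode.
#'
#' @param pointsXy n x 2 matrix of positions, mm.
#' @param massesG iron mass per point, g.
#' @param gantryAngleDeg gantry angle, degrees.
#' @param shiftMt shift field, mT.
#' @param config a [ScannerConfig-class].
#' @param spion a [SpionModel-class].
#' @return named complex vector h2..h9.
#' @export
simulateReadoutTimedomain <- function(pointsXy, massesG, gantryAngleDeg,
                                      shiftMt, config, spion) {
  stopifnot(is(config, "ScannerConfig"), is(spion, "SpionModel"))
  p <- if (is.matrix(pointsXy)) pointsXy else matrix(pointsXy, ncol = 2L)
  tm <- makeTiming(config)
  N <- tm$samplesPerReadout
  tk <- (0:(N - 1L)) / config@sampleRate
  drive <- config@driveAmplitude * cos(2 * pi * config@driveFrequency * tk)
  offs <- fflOffsetField(p, gantryAngleDeg, shiftMt, config)
  M <- numeric(N)
  for (j in seq_along(offs)) {
    M <- M + massesG[j] * spion@signalScale *
      langevin(spion@beta * (offs[j] + drive) / 1000)
  }
  emf <- M[c(2:N, 1L)] - M
  sp <- fft(emf) * (2 / N)
  bins <- as.integer(config@periodsPerReadout) * (2:9) + 1L
  out <- sp[bins]
  names(out) <- paste0("h", 2:9)
  out
}

#' Bin read-outs into a sinogram
#'
#' Console-style binning: per projection, read-outs are assigned to
#' `readoutsPerProjection` uniform shift-field bins spanning
#' `[-shiftFieldPeak, +shiftFieldPeak]`; multiple read-outs in a bin are
#' complex-averaged (phase preserved); empty bins are linearly interpolated
#' from their non-empty neighbours along the shift axis and flagged. The
#' projection angle is the mean measured read-out angle in that projection.
#'
#' @param readouts a [ReadoutSet-class] covering the full sweep.
#' @param config a [ScannerConfig-class]; defaults to the one stored in
#'   `readouts`.
#' @return a [Sinogram-class].
#' @export
binToSinogram <- function(readouts, config = readouts@config) {
  stopifnot(is(readouts, "ReadoutSet"), is(config, "ScannerConfig"))
  nBins <- as.integer(config@readoutsPerProjection)
  nProj <- as.integer(config@projectionsPerImage)
  peak <- config@shiftFieldPeak
  edges <- seq(-peak, peak, length.out = nBins + 1L)
  centers <- (edges[-1L] + edges[-(nBins + 1L)]) / 2
  tm <- makeTiming(config)
  proj <- pmin(pmax(floor(readouts@timestamp / tm$projectionDuration), 0), nProj - 1L) + 1L

  dat <- array(0 + 0i, dim = c(nBins, nProj, 8),
               dimnames = list(NULL, NULL, paste0("h", 2:9)))
  interp <- matrix(FALSE, nBins, nProj)
  angleAxis <- numeric(nProj)
  for (k in seq_len(nProj)) {
    sel <- which(proj == k)
    if (!length(sel)) stop("binToSinogram: projection ", k, " has no read-outs")
    angleAxis[k] <- mean(readouts@angleDeg[sel])
    b <- findInterval(readouts@shiftMt[sel], edges, rightmost.closed = TRUE)
    b <- pmin(pmax(b, 1L), nBins)
    counts <- tabulate(b, nBins)
    if (sum(counts == 0L) > nBins / 2)
      stop("binToSinogram: projection ", k, " has more than 50% empty bins")
    empty <- counts == 0L
    interp[empty, k] <- TRUE
    for (h in 1:8) {
      v <- readouts@harmonics[sel, h]
      acc <- complex(real = as.vector(tapply(Re(v), factor(b, levels = seq_len(nBins)), mean)),
                     imaginary = as.vector(tapply(Im(v), factor(b, levels = seq_len(nBins)), mean)))
      if (any(empty)) {
        ok <- which(!empty)
        re <- approx(centers[ok], Re(acc[ok]), xout = centers[empty], rule = 2)$y
        im <- approx(centers[ok], Im(acc[ok]), xout = centers[empty], rule = 2)$y
        acc[empty] <- complex(real = re, imaginary = im)
      }
      dat[, k, h] <- acc
    }
  }
  new("Sinogram", data = dat, shiftMt = centers, angleDeg = angleAxis,
      interpolated = interp, outlierMask = matrix(FALSE, nBins, nProj),
      provenance = list(config = config, seed = readouts@seed))
}
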