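#' @import methods
#' @importClassesFrom Matrix Matrix dgCMatrix
#' @importFrom Matrix sparseMatrix nnzero
#' @importFrom stats approx fft mvfft median rnorm runif sd coef lm uniroot setNames
#' @importFrom utils head tail
NULL

.positiveScalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0

#' Scanner configuration
#'
#' Holds the operating point of the mechanically rotated FFL scanner: the
#' selection-field gradient, the drive waveform, the shift (FFL translation)
#' waveform, and the acquisition timing counts. All fields are in the units
#' used throughout the package: fields in mT, gradients in T/m, distances in
#' mm, times in seconds.
#'
#' The imaging field of view follows from the shift amplitude and the
#' in-plane gradient: FOV = 2 * shiftFieldPeak / gradientInplane (a T/m
#' gradient times a mm distance is a mT field, so the units collapse
#' conveniently).
#'
#' @slot gradientInplane in-plane selection gradient, T/m.
#' @slot gradientAxial through-plane gradient, T/m (informational in 2D).
#' @slot driveFrequency drive frequency, Hz.
#' @slot driveAmplitude drive field amplitude, mT peak.
#' @slot sampleRate digitizer rate, samples/s.
#' @slot periodsPerReadout drive periods per read-out.
#' @slot readoutsPerProjection read-outs per projection.
#' @slot projectionsPerImage projections per image.
#' @slot shiftFrequency shift (triangle) frequency, Hz.
#' @slot shiftFieldPeak shift field amplitude, mT peak.
#' @slot gantryRpm gantry rotation speed, rev/min.
#' @slot imageSweepDegrees gantry sweep per image, degrees.
#' @name ScannerConfig-class
#' @aliases ScannerConfig-class
#' @exportClass ScannerConfig
setClass("ScannerConfig",
  representation(
    gradientInplane = "numeric",
    gradientAxial = "numeric",
    driveFrequency = "numeric",
    driveAmplitude = "numeric",
    sampleRate = "numeric",
    periodsPerReadout = "numeric",
    readoutsPerProjection = "numeric",
    projectionsPerImage = "numeric",
    shiftFrequency = "numeric",
    shiftFieldPeak = "numeric",
    gantryRpm = "numeric",
    imageSweepDegrees = "numeric"
  )
)

setValidity("ScannerConfig", function(object) {
  msgs <- character()
  for (nm in slotNames(object)) {
    if (!.positiveScalar(slot(object, nm)))
      msgs <- c(msgs, sprintf("slot '%s' must be a positive finite scalar", nm))
  }
  if (length(msgs)) return(msgs)
  spp <- object@sampleRate / object@driveFrequency
  if (abs(spp - round(spp)) > 1e-6)
    msgs <- c(msgs, "sampleRate/driveFrequency must be an integer number of samples per drive period")
  spr <- spp * object@periodsPerReadout
  if (abs(spr - round(spr)) > 1e-6)
    msgs <- c(msgs, "samples per read-out must be an integer")
  if (length(msgs)) msgs else TRUE
})

#' Tracer magnetization model
#'
#' Relaxation-free Langevin model of a superparamagnetic iron oxide
#' nanoparticle (SPION) tracer. The particle is characterized by the
#' steepness of its Langevin argument per unit applied field (`beta`, 1/T)
#' and an arbitrary, calibratable signal scale per gram of iron. `beta` is
#' normally obtained by [calibrateBeta()] so that the third-harmonic
#' offset-field kernel has a stated full width at half maximum.
#'
#' @slot signalScale signal units per g of iron (arbitrary).
#' @slot beta Langevin argument per unit applied field, 1/T.
#' @slot kernelFwhmMt third-harmonic kernel FWHM target, mT, recorded at
#'   calibration time (NA if `beta` was supplied directly).
#' @slot kernelDriveMt drive amplitude (mT) at which the kernel target holds.
#' @slot name free-text particle label.
#' @name SpionModel-class
#' @aliases SpionModel-class
#' @exportClass SpionModel
setClass("SpionModel",
  representation(
    signalScale = "numeric",
    beta = "numeric",
    kernelFwhmMt = "numeric",
    kernelDriveMt = "numeric",
    name = "character"
  )
)

setValidity("SpionModel", function(object) {
  msgs <- character()
  if (!.positiveScalar(object@beta)) msgs <- c(msgs, "beta must be a positive scalar")
  if (!.positiveScalar(object@signalScale)) msgs <- c(msgs, "signalScale must be a positive scalar")
  # the calibration contract: re-measured third-harmonic FWHM within 2% of target
  if (length(msgs) == 0L && is.finite(object@kernelFwhmMt)) {
    fw <- measureKernelFwhm(object@beta, object@kernelDriveMt)
    if (abs(fw - object@kernelFwhmMt) > 0.02 * object@kernelFwhmMt)
      msgs <- c(msgs, sprintf(
        "third-harmonic kernel FWHM %.3f mT deviates more than 2%% from target %.3f mT",
        fw, object@kernelFwhmMt))
  }
  if (length(msgs)) msgs else TRUE
})

#' Ground-truth phantom image
#'
#' A 2D iron concentration map on a uniform grid, with an explicit slab
#' depth so that areal pixels convert to volumes and the phantom carries a
#' meaningful total iron mass. The grid is indexed `[ix, iy]`; the lab-frame
#' coordinate of pixel (i, j) is `((i, j) - origin) * pixelPitch` mm, with
#' the scanner isocenter at coordinate (0, 0).
#'
#' @slot grid matrix of concentrations, mg Fe / mL.
#' @slot pixelPitch pixel edge, mm.
#' @slot depth slab depth, mm.
#' @slot origin grid coordinate (possibly fractional) of the isocenter.
#' @name PhantomImage-class
#' @aliases PhantomImage-class
#' @exportClass PhantomImage
setClass("PhantomImage",
  representation(
    grid = "matrix",
    pixelPitch = "numeric",
    depth = "numeric",
    origin = "numeric"
  )
)

setValidity("PhantomImage", function(object) {
  msgs <- character()
  if (!is.numeric(object@grid)) msgs <- c(msgs, "grid must be numeric")
  else if (any(!is.finite(object@grid))) msgs <- c(msgs, "grid must be finite")
  else if (any(object@grid < 0)) msgs <- c(msgs, "concentrations must be >= 0")
  if (!.positiveScalar(object@pixelPitch)) msgs <- c(msgs, "pixelPitch must be positive")
  if (!.positiveScalar(object@depth)) msgs <- c(msgs, "depth must be positive")
  if (length(object@origin) != 2L) msgs <- c(msgs, "origin must be length 2")
  if (length(msgs)) msgs else TRUE
})

#' One image acquisition worth of read-outs
#'
#' Container for the shortest acquisition units of one gantry sweep. Each
#' read-out (RO) spans a fixed number of drive periods and is summarized by
#' the complex amplitudes of drive harmonics 2..9, its mean gantry angle and
#' mean shift field.
#'
#' @slot harmonics complex matrix, one row per RO, columns h2..h9.
#' @slot angleDeg mean gantry angle per RO, degrees.
#' @slot shiftMt mean shift field per RO, mT.
#' @slot timestamp RO mid-time, s from sweep start.
#' @slot spiked logical, TRUE where a transient spike was injected (ground
#'   truth from the generator; empty hardware would not know this).
#' @slot config the [ScannerConfig-class] used.
#' @slot seed integer seed used for noise (NA if noiseless).
#' @name ReadoutSet-class
#' @aliases ReadoutSet-class
#' @exportClass ReadoutSet
setClass("ReadoutSet",
  representation(
    harmonics = "matrix",
    angleDeg = "numeric",
    shiftMt = "numeric",
    timestamp = "numeric",
    spiked = "logical",
    config = "ScannerConfig",
    seed = "numeric"
  )
)

setValidity("ReadoutSet", function(object) {
  msgs <- character()
  if (!is.complex(object@harmonics)) msgs <- c(msgs, "harmonics must be complex")
  if (ncol(object@harmonics) != 8L) msgs <- c(msgs, "harmonics must have 8 columns (h2..h9)")
  n <- nrow(object@harmonics)
  if (length(object@angleDeg) != n || length(object@shiftMt) != n)
    msgs <- c(msgs, "angleDeg/shiftMt length must match number of read-outs")
  if (length(msgs)) msgs else TRUE
})

#' Sinogram container
#'
#' Per-harmonic complex tables indexed by (shift bin, projection angle), the
#' input to tomographic reconstruction. Carries the bin-center shift axis,
#' the mean measured angle per projection, a flag matrix marking bins that
#' were empty and filled by interpolation, an outlier mask written by the
#' despiker, and a provenance list (config snapshot, seed).
#'
#' @slot data complex array `[shift bin, projection, harmonic]` with
#'   harmonic dimnames "h2".."h9".
#' @slot shiftMt shift-field bin centers, mT, strictly increasing.
#' @slot angleDeg mean measured angle per projection, degrees.
#' @slot interpolated logical matrix of bins filled by interpolation.
#' @slot outlierMask logical matrix written by [despikeSinogram()].
#' @slot provenance list (config, seed, notes).
#' @name Sinogram-class
#' @aliases Sinogram-class
#' @exportClass Sinogram
setClass("Sinogram",
  representation(
    data = "array",
    shiftMt = "numeric",
    angleDeg = "numeric",
    interpolated = "matrix",
    outlierMask = "matrix",
    provenance = "list"
  )
)

setValidity("Sinogram", function(object) {
  msgs <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msgs <- c(msgs, "data must be a 3D array [bin, projection, harmonic]")
  else {
    if (length(object@shiftMt) != d[1L]) msgs <- c(msgs, "shiftMt length must match bin count")
    if (length(object@angleDeg) != d[2L]) msgs <- c(msgs, "angleDeg length must match projection count")
    if (any(diff(object@shiftMt) <= 0)) msgs <- c(msgs, "shiftMt must be strictly increasing")
  }
  if (!is.complex(object@data)) msgs <- c(msgs, "data must be complex")
  if (length(msgs)) msgs else TRUE
})

#' Reconstructed image
#'
#' A square 2D real-valued image (arbitrary units proportional to g Fe per
#' pixel) with its field of view and pixel pitch, plus the reconstruction
#' method label and provenance.
#'
#' @slot values square numeric matrix `[ix, iy]`.
#' @slot fovMm field of view (grid extent), mm; equals pitch times grid size.
#' @slot pixelPitchMm pixel edge, mm.
#' @slot method "inverse_radon" or "iterative".
#' @slot provenance list of reconstruction parameters.
#' @name ReconImage-class
#' @aliases ReconImage-class
#' @exportClass ReconImage
setClass("ReconImage",
  representation(
    values = "matrix",
    fovMm = "numeric",
    pixelPitchMm = "numeric",
    method = "character",
    provenance = "list"
  )
)

setValidity("ReconImage", function(object) {
  msgs <- character()
  if (nrow(object@values) != ncol(object@values)) msgs <- c(msgs, "image must be square")
  if (!object@method %in% c("inverse_radon", "iterative"))
    msgs <- c(msgs, "method must be 'inverse_radon' or 'iterative'")
  if (abs(object@fovMm - object@pixelPitchMm * nrow(object@values)) > 1e-6 * object@fovMm)
    msgs <- c(msgs, "fovMm must equal pixelPitchMm * grid size")
  if (length(msgs)) msgs else TRUE
})

#' Sparse forward operator for the iterative reconstruction
#'
#' Linear operator mapping image pixels to sinogram-bin measurements. Each
#' row is the FFL at one (shift, angle) position, convolved perpendicular to
#' the line with a Gaussian of standard deviation `kernelStdMm`, truncated
#' at 4 standard deviations, and rasterized on the image grid.
#'
#' @slot A sparse nonnegative matrix (rows = measurements, cols = pixels).
#' @slot angleDeg angle per row, degrees.
#' @slot shiftMt shift field per row, mT.
#' @slot kernelStdMm Gaussian FFL kernel standard deviation, mm.
#' @slot gridN image grid size (image is gridN x gridN).
#' @slot pixelPitchMm pixel edge, mm.
#' @slot gradientInplane gradient used to map shift field to line offset, T/m.
#' @name SystemMatrix-class
#' @aliases SystemMatrix-class
#' @exportClass SystemMatrix
setClass("SystemMatrix",
  representation(
    A = "Matrix",
    angleDeg = "numeric",
    shiftMt = "numeric",
    kernelStdMm = "numeric",
    gridN = "numeric",
    pixelPitchMm = "numeric",
    gradientInplane = "numeric"
  )
)

setValidity("SystemMatrix", function(object) {
  msgs <- character()
  if (ncol(object@A) != object@gridN^2) msgs <- c(msgs, "A column count must equal gridN^2")
  if (nrow(object@A) != length(object@angleDeg) || nrow(object@A) != length(object@shiftMt))
    msgs <- c(msgs, "row metadata must match row count")
  if (!.positiveScalar(object@kernelStdMm)) msgs <- c(msgs, "kernelStdMm must be positive")
  if (length(msgs)) msgs else TRUE
})
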