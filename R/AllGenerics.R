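#' @rdname fovMm
#' @export
setGeneric("fovMm", function(x) standardGeneric("fovMm"))

#' @rdname pitchMm
#' @export
setGeneric("pitchMm", function(x) standardGeneric("pitchMm"))

#' @rdname gridValues
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname ironMass
#' @export
setGeneric("ironMass", function(x) standardGeneric("ironMass"))

#' Field of view in millimetres
#'
#' For a [ScannerConfig-class] the FOV implied by the shift amplitude and
#' in-plane gradient (2 * shiftFieldPeak / gradientInplane); for images and
#' phantoms the grid extent (pitch times grid size).
#'
#' @param x a ScannerConfig, PhantomImage or ReconImage.
#' @return numeric scalar, mm.
#' @name fovMm
#' @export fovMm
NULL

#' Pixel pitch in millimetres
#' @param x a PhantomImage or ReconImage.
#' @return numeric scalar, mm.
#' @name pitchMm
#' @export pitchMm
NULL

#' Underlying grid values
#'
#' The raw 2D matrix of a phantom (concentrations, mg/mL) or reconstructed
#' image (a.u.), indexed `[ix, iy]`.
#' @param x a PhantomImage or ReconImage.
#' @return numeric matrix.
#' @name gridValues
#' @export gridValues
NULL

#' Total iron mass of a phantom
#'
#' Sum over pixels of concentration times pixel volume (pitch^2 * depth).
#' @param x a PhantomImage.
#' @return total iron mass in grams.
#' @name ironMass
#' @export ironMass
NULL

setMethod("fovMm", "ScannerConfig", function(x) 2 * x@shiftFieldPeak / x@gradientInplane)
setMethod("fovMm", "PhantomImage", function(x) nrow(x@grid) * x@pixelPitch)
setMethod("fovMm", "ReconImage", function(x) x@fovMm)

setMethod("pitchMm", "PhantomImage", function(x) x@pixelPitch)
setMethod("pitchMm", "ReconImage", function(x) x@pixelPitchMm)

setMethod("gridValues", "PhantomImage", function(x) x@grid)
setMethod("gridValues", "ReconImage", function(x) x@values)

setMethod("ironMass", "PhantomImage", function(x) {
  # conc mg/mL * volume mm^3 -> mg: 1 mm^3 = 1e-3 mL; then mg -> g
  sum(x@grid) * x@pixelPitch^2 * x@depth * 1e-3 * 1e-3
})

setMethod("show", "ScannerConfig", function(object) {
  cat("ScannerConfig\n")
  cat(sprintf("  gradient (in-plane): %.3g T/m   drive: %.4g mT @ %.5g kHz\n",
              object@gradientInplane, object@driveAmplitude, object@driveFrequency / 1e3))
  cat(sprintf("  shift: %.4g mT @ %.3g Hz  ->  FOV %.4g mm\n",
              object@shiftFieldPeak, object@shiftFrequency, fovMm(object)))
  cat(sprintf("  %d ROs x %d projections, %d periods/RO, gantry %.3g RPM, %g deg sweep\n",
              as.integer(object@readoutsPerProjection), as.integer(object@projectionsPerImage),
              as.integer(object@periodsPerReadout), object@gantryRpm, object@imageSweepDegrees))
})

setMethod("show", "SpionModel", function(object) {
  cat(sprintf("SpionModel '%s': beta = %.5g /T, signalScale = %.3g /gFe", object@name,
              object@beta, object@signalScale))
  if (is.finite(object@kernelFwhmMt))
    cat(sprintf(" (h3 kernel FWHM %.3g mT @ %.3g mT drive)", object@kernelFwhmMt, object@kernelDriveMt))
  cat("\n")
})

setMethod("show", "PhantomImage", function(object) {
  cat(sprintf("PhantomImage %dx%d @ %.3g mm pitch (%.4g mm extent), depth %.3g mm\n",
              nrow(object@grid), ncol(object@grid), object@pixelPitch,
              fovMm(object), object@depth))
  cat(sprintf("  iron mass %.4g ug, max conc %.4g mg/mL\n",
              ironMass(object) * 1e6, max(object@grid)))
})

setMethod("show", "ReadoutSet", function(object) {
  cat(sprintf("ReadoutSet: %d read-outs, angles %.2f..%.2f deg, shift %.3g..%.3g mT\n",
              nrow(object@harmonics), min(object@angleDeg), max(object@angleDeg),
              min(object@shiftMt), max(object@shiftMt)))
  if (any(object@spiked)) cat(sprintf("  %d spiked read-outs\n", sum(object@spiked)))
})

setMethod("show", "Sinogram", function(object) {
  d <- dim(object@data)
  cat(sprintf("Sinogram: %d shift bins x %d projections x %d harmonics\n", d[1], d[2], d[3]))
  cat(sprintf("  shift %.4g..%.4g mT, angles %.2f..%.2f deg, %d interpolated bins, %d masked\n",
              min(object@shiftMt), max(object@shiftMt), min(object@angleDeg), max(object@angleDeg),
              sum(object@interpolated), sum(object@outlierMask)))
})

setMethod("show", "ReconImage", function(object) {
  cat(sprintf("ReconImage (%s): %dx%d px, FOV %.4g mm, pitch %.3g mm, range [%.3g, %.3g]\n",
              object@method, nrow(object@values), ncol(object@values), object@fovMm,
              object@pixelPitchMm, min(object@values), max(object@values)))
})

setMethod("show", "SystemMatrix", function(object) {
  cat(sprintf("SystemMatrix: %d measurements x %d pixels (grid %dx%d), kernel std %.3g mm, %.3g%% dense\n",
              nrow(object@A), ncol(object@A), as.integer(object@gridN), as.integer(object@gridN),
              object@kernelStdMm, 100 * Matrix::nnzero(object@A) / prod(dim(object@A))))
})
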