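# Plain-text persistence: sinograms as a JSON container (per-harmonic
# real/imaginary tables, axes, flags, config snapshot, seed), images and
# phantoms as CSV grids with a JSON sidecar, and optional float TIFF
# export when the 'tiff' package is available.

#' Write / read a sinogram container
#'
#' JSON layout mirrors the acquisition structure: `harmonics/h2..h9` hold
#' the real and imaginary parts of each (shift bin x projection) table,
#' `axes` the shift (mT) and angle (deg) axes, `flags` the interpolation
#' and outlier masks, `meta` a flat config snapshot plus the seed.
#'
#' @param sinogram a [Sinogram-class].
#' @param path output path (conventionally `.json`).
#' @return `writeSinogram` returns `path` invisibly; `readSinogram`
#'   returns the [Sinogram-class].
#' @export
writeSinogram <- function(sinogram, path) {
  stopifnot(is(sinogram, "Sinogram"))
  cfg <- sinogram@provenance$config
  harm <- dimnames(sinogram@data)[[3L]]
  obj <- list(
    harmonics = setNames(lapply(harm, function(h) {
      pl <- sinogram@data[, , h]
      list(re = unname(as.data.frame(Re(pl))), im = unname(as.data.frame(Im(pl))))
    }), harm),
    axes = list(shift_mT = sinogram@shiftMt, angle_deg = sinogram@angleDeg),
    flags = list(interpolated = unname(as.data.frame(sinogram@interpolated * 1L)),
                 outlier = unname(as.data.frame(sinogram@outlierMask * 1L))),
    meta = list(
      seed = sinogram@provenance$seed,
      config = if (!is.null(cfg))
        as.list(sapply(slotNames(cfg), function(nm) slot(cfg, nm)))
    )
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  harm <- names(obj$harmonics)
  nb <- length(obj$axes$shift_mT)
  np <- length(obj$axes$angle_deg)
  dat <- array(0 + 0i, dim = c(nb, np, length(harm)),
               dimnames = list(NULL, NULL, harm))
  for (h in harm) {
    dat[, , h] <- complex(real = as.matrix(obj$harmonics[[h]]$re),
                          imaginary = as.matrix(obj$harmonics[[h]]$im))
  }
  cfg <- if (!is.null(obj$meta$config))
    do.call(scannerConfig, lapply(obj$meta$config, as.numeric))
  new("Sinogram", data = dat,
      shiftMt = as.numeric(obj$axes$shift_mT),
      angleDeg = as.numeric(obj$axes$angle_deg),
      interpolated = as.matrix(obj$flags$interpolated) > 0,
      outlierMask = as.matrix(obj$flags$outlier) > 0,
      provenance = list(config = cfg,
                        seed = if (is.null(obj$meta$seed)) NA_real_
                               else as.numeric(obj$meta$seed)))
}

#' Write / read a reconstructed image (CSV grid + JSON sidecar)
#'
#' The grid goes to `<path>.csv` (comma-separated, one row per x index)
#' and the metadata (FOV, pitch, method, provenance) to `<path>.json`.
#'
#' @param image a [ReconImage-class].
#' @param path base path (extensions are appended).
#' @return `writeReconImage` returns the base path invisibly.
#' @export
writeReconImage <- function(image, path) {
  stopifnot(is(image, "ReconImage"))
  utils::write.table(image@values, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(fov_mm = image@fovMm, pixel_pitch_mm = image@pixelPitchMm,
               method = image@method,
               provenance = image@provenance[
                 vapply(image@provenance, function(x)
                   is.numeric(x) || is.character(x) || is.logical(x), logical(1))])
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeReconImage
#' @export
readReconImage <- function(path) {
  v <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  dimnames(v) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("ReconImage", values = v, fovMm = meta$fov_mm,
      pixelPitchMm = meta$pixel_pitch_mm, method = meta$method,
      provenance = as.list(meta$provenance))
}

#' Export an image or phantom grid as 32-bit float TIFF
#'
#' Requires the suggested 'tiff' package. The TIFF writer stores values in
#' `[0, 1]`, so the grid is scaled by its value range; the offset and
#' scale needed to recover physical values are written to a `<path>.json`
#' sidecar (`value = offset + scale * stored`).
#'
#' @param x a [ReconImage-class] or [PhantomImage-class].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
writeGridTiff <- function(x, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writeGridTiff: the 'tiff' package is not installed")
  v <- gridValues(x)
  off <- min(v)
  sc <- max(v) - off
  if (sc == 0) sc <- 1
  tiff::writeTIFF((v - off) / sc, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(offset = off, scale = sc,
               pixel_pitch_mm = pitchMm(x), fov_mm = fovMm(x))
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}
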