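# Forward-model iterative reconstruction: a sparse linear operator built
# from the known FFL position per measurement (shift field / gradient,
# gantry angle) with a Gaussian point-spread kernel perpendicular to the
# line, inverted by a fixed number of Jacobi-preconditioned conjugate
# gradient iterations on the normal equations.

#' Build the sparse forward model
#'
#' One row per measurement (sinogram bin or read-out): the FFL at the
#' stated gantry angle, offset perpendicular to the line by
#' `-shift / gradient` mm, convolved perpendicular-to-line with a Gaussian
#' of standard deviation `kernelStdMm` (an approximation of the imager's
#' native point-spread), truncated at 4 sigma and rasterized on the image
#' grid. Pixel weights are `pitch * exp(-d^2 / (2 sigma^2))` with `d` the
#' perpendicular pixel-to-line distance, so every row of a line fully
#' inside the grid carries the same line-integral normalization.
#'
#' @param anglesDeg gantry angle per measurement, degrees.
#' @param shiftsMt shift field per measurement, mT.
#' @param config a [ScannerConfig-class] (provides gradient and FOV).
#' @param kernelStdMm Gaussian FFL kernel standard deviation, mm
#'   (default 7); must be > 0.
#' @param gridN image grid size (default 132).
#' @return a [SystemMatrix-class].
#' @export
buildForwardModel <- function(anglesDeg, shiftsMt, config, kernelStdMm = 7,
                              gridN = 132) {
  stopifnot(is(config, "ScannerConfig"))
  if (length(anglesDeg) != length(shiftsMt))
    stop("buildForwardModel: anglesDeg and shiftsMt must have equal length")
  if (!is.numeric(kernelStdMm) || kernelStdMm <= 0)
    stop("buildForwardModel: kernelStdMm must be > 0")
  G <- config@gradientInplane
  fov <- fovMm(config)
  pitch <- fov / gridN
  xc <- .gridCenters(gridN, pitch)
  X <- matrix(xc, gridN, gridN)
  Y <- matrix(xc, gridN, gridN, byrow = TRUE)
  r <- -shiftsMt / G
  cut <- 4 * kernelStdMm
  nRows <- length(anglesDeg)

  ilist <- vector("list", nRows)
  jlist <- vector("list", nRows)
  xlist <- vector("list", nRows)
  # group rows by angle so the pixel projection is computed once per angle
  byAngle <- split(seq_len(nRows), anglesDeg)
  for (rows in byAngle) {
    th <- anglesDeg[rows[1L]] * pi / 180
    u <- as.vector(-X * sin(th) + Y * cos(th))
    for (i in rows) {
      d <- u - r[i]
      sel <- which(abs(d) <= cut)
      if (length(sel)) {
        ilist[[i]] <- rep.int(i, length(sel))
        jlist[[i]] <- sel
        xlist[[i]] <- pitch * exp(-d[sel]^2 / (2 * kernelStdMm^2))
      }
    }
  }
  ii <- unlist(ilist); jj <- unlist(jlist); xx <- unlist(xlist)
  A <- if (length(ii))
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nRows, gridN^2),
                         repr = "C")
  else
    as(Matrix::Matrix(0, nRows, gridN^2, sparse = TRUE), "CsparseMatrix")
  new("SystemMatrix", A = A, angleDeg = anglesDeg, shiftMt = shiftsMt,
      kernelStdMm = kernelStdMm, gridN = gridN, pixelPitchMm = pitch,
      gradientInplane = G)
}

#' Forward model rows matching a sinogram's bin layout
#'
#' Convenience wrapper: one row per (shift bin, projection) pair in the
#' sinogram's storage order (shift bin fastest), so the flattened
#' phase-aligned plane is directly the measurement vector.
#'
#' @param sinogram a [Sinogram-class].
#' @param kernelStdMm,gridN passed to [buildForwardModel()].
#' @return a [SystemMatrix-class].
#' @export
forwardModelForSinogram <- function(sinogram, kernelStdMm = 7, gridN = 132) {
  stopifnot(is(sinogram, "Sinogram"))
  cfg <- sinogram@provenance$config
  if (is.null(cfg)) stop("forwardModelForSinogram: sinogram provenance lacks the scanner config")
  nb <- length(sinogram@shiftMt)
  buildForwardModel(rep(sinogram@angleDeg, each = nb),
                    rep.int(sinogram@shiftMt, length(sinogram@angleDeg)),
                    cfg, kernelStdMm = kernelStdMm, gridN = gridN)
}

#' Iterative reconstruction by truncated preconditioned conjugate gradients
#'
#' Solves the normal equations `A'A x = A'b` with Jacobi (diagonal)
#' preconditioning, a zero initial guess, and exactly `nIter` iterations —
#' no early stopping; the fixed truncation (default 15) is the
#' regularization, balancing sharpness against amplification of ringing
#' artifacts. `nIter = 0` returns the zero image.
#'
#' @param measurements real vector, one per row of `A` (the phase-aligned
#'   real part of the harmonic plane, flattened in the operator's row
#'   order).
#' @param A a [SystemMatrix-class].
#' @param nIter conjugate gradient iterations (default 15).
#' @param smoothingFwhm optional post-reconstruction Gaussian FWHM, mm
#'   (default 0 = none).
#' @return a [ReconImage-class] with method "iterative"; the per-iteration
#'   normal-equation residual norms are in `provenance$residuals`.
#' @export
iterativeRecon <- function(measurements, A, nIter = 15, smoothingFwhm = 0) {
  stopifnot(is(A, "SystemMatrix"))
  b <- as.numeric(measurements)
  if (length(b) != nrow(A@A))
    stop("iterativeRecon: measurement length does not match operator rows")
  M <- A@A
  Atb <- as.numeric(Matrix::crossprod(M, b))
  dA <- as.numeric(Matrix::colSums(M^2))    # diag(A'A), Jacobi preconditioner
  dA[dA <= 0] <- max(dA, 1)                  # pixels untouched by any row
  x <- numeric(ncol(M))
  r <- Atb                                   # residual of the normal equations
  z <- r / dA
  p <- z
  rz <- sum(r * z)
  resid <- numeric(nIter)
  if (nIter > 0) {
    for (it in seq_len(nIter)) {
      Ap <- as.numeric(Matrix::crossprod(M, M %*% p))
      alpha <- rz / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      resid[it] <- sqrt(sum(r^2))
      z <- r / dA
      rzNew <- sum(r * z)
      beta <- rzNew / rz
      rz <- rzNew
      p <- z + beta * p
    }
  }
  img <- matrix(x, A@gridN, A@gridN)
  out <- new("ReconImage", values = img, fovMm = A@gridN * A@pixelPitchMm,
             pixelPitchMm = A@pixelPitchMm, method = "iterative",
             provenance = list(nIter = nIter, kernelStdMm = A@kernelStdMm,
                               residuals = resid))
  if (smoothingFwhm > 0) out <- smoothImage(out, smoothingFwhm) else out
}

#' Iterative reconstruction of a sinogram harmonic
#'
#' End-to-end convenience: phase-aligns the harmonic plane, builds (or
#' reuses) the forward model matching the sinogram layout, runs
#' [iterativeRecon()], and applies the post-reconstruction smoothing.
#'
#' @param sinogram a preprocessed [Sinogram-class].
#' @param harmonic harmonic number (default 3).
#' @param A optional precomputed [SystemMatrix-class] from
#'   [forwardModelForSinogram()] (reuse across phantoms sharing a config).
#' @param kernelStdMm,gridN forwarded when `A` is NULL.
#' @param nIter conjugate gradient iterations (default 15).
#' @param smoothingFwhm Gaussian FWHM, mm (default 1.5).
#' @return a [ReconImage-class].
#' @export
iterativeReconSinogram <- function(sinogram, harmonic = 3, A = NULL,
                                   kernelStdMm = 7, gridN = 132, nIter = 15,
                                   smoothingFwhm = 1.5) {
  stopifnot(is(sinogram, "Sinogram"))
  key <- paste0("h", harmonic)
  if (!key %in% dimnames(sinogram@data)[[3L]])
    stop("iterativeReconSinogram: harmonic plane ", key, " not present")
  if (is.null(A)) A <- forwardModelForSinogram(sinogram, kernelStdMm, gridN)
  b <- as.vector(phaseAlign(sinogram@data[, , key])$real)
  out <- iterativeRecon(b, A, nIter = nIter, smoothingFwhm = smoothingFwhm)
  out@provenance$harmonic <- harmonic
  out@provenance$seed <- sinogram@provenance$seed
  out
}
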