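# Quantitative validation metrology: two-peak contrast, resolution from a
# line-pair series, detection limit from a dilution regression, FOV
# calibration, image SNR, and the gradiometer feedthrough formula.

# topographic prominence of every strict-or-plateau local maximum
.localMaxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  which(v[2:(n - 1L)] >= v[1:(n - 2L)] & v[2:(n - 1L)] >= v[3:n]) + 1L
}

.prominence <- function(v, peaks) {
  vapply(peaks, function(i) {
    h <- v[i]
    # walk left until a higher point; key saddle is the minimum on the way
    left <- if (i > 1L) {
      seg <- v[(i - 1L):1L]
      stopAt <- which(seg > h)[1L]
      if (is.na(stopAt)) min(seg) else min(seg[seq_len(stopAt)])
    } else h
    right <- if (i < length(v)) {
      seg <- v[(i + 1L):length(v)]
      stopAt <- which(seg > h)[1L]
      if (is.na(stopAt)) min(seg) else min(seg[seq_len(stopAt)])
    } else h
    h - max(left, right)
  }, numeric(1))
}

#' Two-peak contrast of a line profile
#'
#' Identifies the two most prominent local maxima of the profile
#' (topographic prominence, robust to the ringing sidelobes iterative
#' reconstructions produce), the minimum signal between them, and
#' evaluates the contrast statistic
#' `C = 1 - Smin / (0.5 * (SmaxLeft + SmaxRight))`. A contrast above 0.5
#' is the conventional "resolved" threshold. Invariant to positive
#' rescaling of the profile.
#'
#' @param profile numeric signal vector, length >= 5.
#' @param positions optional positions (mm) matching `profile`.
#' @return list with `C`, `sMin`, `sMaxLeft`, `sMaxRight`,
#'   `peakPositions` (mm, or indices when positions are absent).
#' @examples
#' contrastMetric(c(0, 1, 0.45, 0.8, 0))$C  # 0.5
#' @export
contrastMetric <- function(profile, positions = seq_along(profile)) {
  if (length(profile) < 5L) stop("contrastMetric: profile too short")
  if (length(positions) != length(profile))
    stop("contrastMetric: positions must match profile length")
  pk <- .localMaxima(profile)
  if (length(pk) < 2L)
    stop("contrastMetric: fewer than two local maxima (unresolved profile)")
  prom <- .prominence(profile, pk)
  top2 <- pk[order(prom, decreasing = TRUE)[1:2]]
  top2 <- sort(top2)
  between <- profile[top2[1L]:top2[2L]]
  sMin <- min(between)
  sL <- profile[top2[1L]]; sR <- profile[top2[2L]]
  list(C = 1 - sMin / (0.5 * (sL + sR)),
       sMin = sMin, sMaxLeft = sL, sMaxRight = sR,
       peakPositions = positions[top2])
}

#' Central line profile of a reconstructed image
#'
#' The profile through the image middle, perpendicular to vertically
#' oriented features: along x at y = 0 (`axis = "x"`, the average of the
#' two middle columns on an even grid) or along y at x = 0 (`axis = "y"`).
#'
#' @param image a [ReconImage-class].
#' @param axis "x" or "y".
#' @return list with `positions` (mm) and `values`.
#' @export
centralProfile <- function(image, axis = c("x", "y")) {
  axis <- match.arg(axis)
  v <- gridValues(image)
  n <- nrow(v)
  mid <- if (n %% 2L == 0L) c(n / 2, n / 2 + 1L) else (n + 1L) / 2
  prof <- if (axis == "x") rowMeans(v[, mid, drop = FALSE])
          else colMeans(v[mid, , drop = FALSE])
  list(positions = .gridCenters(n, pitchMm(image)), values = prof)
}

#' Resolved separation from a line-pair image series
#'
#' Extracts the central profile perpendicular to the tubes from each
#' reconstruction, computes the two-peak contrast per separation, and
#' returns the smallest separation with C > 0.5. Profiles without two
#' local maxima count as unresolved (C = NA).
#'
#' @param images list of [ReconImage-class], one per separation.
#' @param separations sorted ascending separations, mm.
#' @param axis profile axis passed to [centralProfile()].
#' @return list with `table` (data.frame separation, C), `resolvedMm`
#'   (smallest resolved separation, or NA when none resolves) and
#'   `resolved` (logical).
#' @export
resolutionFromSeries <- function(images, separations, axis = "x") {
  if (length(images) != length(separations))
    stop("resolutionFromSeries: one image per separation required")
  if (is.unsorted(separations))
    stop("resolutionFromSeries: separations must be sorted ascending")
  C <- vapply(images, function(im) {
    pr <- centralProfile(im, axis)
    res <- tryCatch(contrastMetric(pr$values, pr$positions),
                    error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$C
  }, numeric(1))
  ok <- which(!is.na(C) & C > 0.5)
  list(table = data.frame(separation = separations, C = C),
       resolvedMm = if (length(ok)) separations[min(ok)] else NA_real_,
       resolved = length(ok) > 0L)
}

#' Detection limit from a dilution regression
#'
#' Ordinary least squares of peak image signal against iron mass; the
#' limit of detection at k sigma is the mass where the fitted line crosses
#' k times the empty-bore noise standard deviation (intercept included, so
#' a non-zero baseline signal shifts the crossing).
#'
#' @param massesG iron masses, g (>= 3 points).
#' @param peakSignals peak image signal per mass, a.u.
#' @param noiseSigma empty-bore image noise standard deviation, a.u. (> 0).
#' @return list with `slope`, `intercept`, `rSquared`, `noiseSigma`,
#'   `lod1SigmaG`, `lod5SigmaG` (g Fe).
#' @examples
#' detectionLimit(c(1, 2, 3), 2 * c(1, 2, 3), 10)  # lod1 = 5, lod5 = 25
#' @export
detectionLimit <- function(massesG, peakSignals, noiseSigma) {
  if (length(massesG) < 3L) stop("detectionLimit: need at least 3 points")
  if (!is.numeric(noiseSigma) || noiseSigma <= 0)
    stop("detectionLimit: noiseSigma must be > 0")
  fit <- lm(peakSignals ~ massesG)
  a <- unname(coef(fit)[2L]); b <- unname(coef(fit)[1L])
  if (a <= 0) stop("detectionLimit: non-positive slope (no sensitivity)")
  r2 <- suppressWarnings(summary(fit))$r.squared  # exact fits warn harmlessly
  list(slope = a, intercept = b, rSquared = r2, noiseSigma = noiseSigma,
       lod1SigmaG = (1 * noiseSigma - b) / a,
       lod5SigmaG = (5 * noiseSigma - b) / a)
}

#' Field-of-view calibration from a known feature
#'
#' A feature of known physical extent spanning a measured number of pixels
#' calibrates the full image FOV: `FOV = extent * gridN / pixels`.
#'
#' @param image a [ReconImage-class] (provides the grid size).
#' @param knownFeatureExtentMm known physical extent, mm.
#' @param measuredExtentPx measured extent in pixels (>= 2; may be
#'   fractional after subpixel peak localization).
#' @return calibrated FOV, mm.
#' @examples
#' # a 136 mm ring spanning 99 of 132 pixels: FOV ~ 181.3 mm
#' 136 * 132 / 99
#' @export
fovCalibration <- function(image, knownFeatureExtentMm, measuredExtentPx) {
  stopifnot(is(image, "ReconImage"))
  if (measuredExtentPx < 2) stop("fovCalibration: need at least 2 pixels")
  knownFeatureExtentMm * nrow(gridValues(image)) / measuredExtentPx
}

#' Distance between the two outermost profile peaks, in pixels
#'
#' Finds the outermost prominent local maxima of the central profile
#' (e.g. the ring line centers of the FOV glyph) and returns their
#' distance in pixel units with parabolic subpixel refinement.
#'
#' @param image a [ReconImage-class].
#' @param axis profile axis (default "y", crossing the ring top/bottom).
#' @param minProminenceFrac peaks below this fraction of the profile
#'   maximum prominence are ignored.
#' @return extent in pixels (fractional).
#' @export
measureExtentPx <- function(image, axis = "y", minProminenceFrac = 0.3) {
  pr <- centralProfile(image, axis)
  v <- pr$values
  pk <- .localMaxima(v)
  if (length(pk) < 2L) stop("measureExtentPx: fewer than two peaks")
  prom <- .prominence(v, pk)
  pk <- pk[prom >= minProminenceFrac * max(prom)]
  if (length(pk) < 2L) stop("measureExtentPx: fewer than two prominent peaks")
  refine <- function(i) {
    if (i <= 1L || i >= length(v)) return(as.numeric(i))
    denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
    if (denom >= 0) return(as.numeric(i))
    i + 0.5 * (v[i - 1L] - v[i + 1L]) / denom
  }
  abs(refine(max(pk)) - refine(min(pk)))
}

#' Gradiometer feedthrough attenuation
#'
#' `A = (vRxOut / vRxIn) * (iDriveIn / iDriveOut)`, reported as
#' `20 log10(A)` in dB relative to carrier (dBc). "Out" quantities are
#' measured with the receive coil withdrawn (maximum induced voltage),
#' "In" with the coil nulled in its gradiometric position.
#'
#' @param vRxOut,vRxIn receive-coil voltages, V (> 0).
#' @param iDriveIn,iDriveOut drive currents, A (> 0).
#' @return attenuation, dBc.
#' @examples
#' feedthroughAttenuation(10, 1, 10, 1)  # 40 dBc
#' @export
feedthroughAttenuation <- function(vRxOut, vRxIn, iDriveIn, iDriveOut) {
  args <- c(vRxOut, vRxIn, iDriveIn, iDriveOut)
  if (any(!is.finite(args)) || any(args <= 0))
    stop("feedthroughAttenuation: all arguments must be positive")
  20 * log10((vRxOut / vRxIn) * (iDriveIn / iDriveOut))
}

#' Image signal-to-noise ratio
#'
#' Peak value of the image divided by the standard deviation of all
#' in-FOV voxels of an empty-bore noise image on the same grid.
#'
#' @param image a [ReconImage-class].
#' @param noiseImage an empty-bore [ReconImage-class], same grid.
#' @return SNR, dimensionless.
#' @export
imageSNR <- function(image, noiseImage) {
  stopifnot(is(image, "ReconImage"), is(noiseImage, "ReconImage"))
  if (!identical(dim(gridValues(image)), dim(gridValues(noiseImage))))
    stop("imageSNR: images must share a grid")
  n <- nrow(gridValues(noiseImage))
  xc <- .gridCenters(n, pitchMm(noiseImage))
  inFov <- outer(xc^2, xc^2, "+") <= (fovMm(noiseImage) / 2)^2
  s <- sd(gridValues(noiseImage)[inFov])
  if (s == 0) stop("imageSNR: zero noise standard deviation")
  max(gridValues(image)) / s
}
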