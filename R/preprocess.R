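# Sinogram cleaning: per-projection complex linear baseline subtraction
# (no-signal assumption at the FOV perimeter) and moving-median scaled-MAD
# despiking of shift-system transients.

#' Subtract a complex linear baseline from one projection
#'
#' Fits the complex line through (mean index of the first 2 points, mean of
#' the first 2 values) and (mean index of the last 2 points, mean of the
#' last 2 values) and subtracts it — the "no signal at the perimeter of the
#' FOV" assumption. After subtraction the means of the first two and last
#' two points are zero (to rounding), and the operation is idempotent.
#'
#' @param projection complex (or numeric) vector, length >= 4.
#' @return complex vector of the same length.
#' @examples
#' subtractBaseline(as.complex(1:10))  # a pure ramp maps to zero
#' @export
subtractBaseline <- function(projection) {
  n <- length(projection)
  if (n < 4L) stop("subtractBaseline: need at least 4 points")
  x <- as.complex(projection)
  m1 <- mean(x[1:2]);            i1 <- 1.5
  m2 <- mean(x[(n - 1L):n]);     i2 <- n - 0.5
  slope <- (m2 - m1) / (i2 - i1)
  x - (m1 + slope * (seq_len(n) - i1))
}

#' Subtract baselines from every projection of a sinogram
#'
#' Applies [subtractBaseline()] column-wise (one column = one projection)
#' to the selected harmonic planes.
#'
#' @param sinogram a [Sinogram-class].
#' @param harmonics harmonic numbers to clean (default all stored, 2:9).
#' @return the cleaned [Sinogram-class].
#' @export
subtractBaselineSinogram <- function(sinogram, harmonics = 2:9) {
  stopifnot(is(sinogram, "Sinogram"))
  for (h in harmonics) {
    plane <- sinogram@data[, , paste0("h", h)]
    sinogram@data[, , paste0("h", h)] <- apply(plane, 2L, subtractBaseline)
  }
  sinogram
}

# 3-element moving median / scaled MAD of a magnitude vector; at the
# boundaries the window is the three nearest elements, so the endpoints
# keep a full window and remain flaggable
.movOutlier3 <- function(m) {
  n <- length(m)
  flag <- logical(n)
  if (n < 3L) return(list(flag = flag))
  for (i in seq_len(n)) {
    c0 <- min(max(i, 2L), n - 1L)
    w <- m[(c0 - 1L):(c0 + 1L)]
    mi <- median(w)
    s <- 1.4826 * median(abs(w - mi))
    flag[i] <- abs(m[i] - mi) > 3 * s   # MAD = 0: zero deviation never flags
  }
  list(flag = flag)
}

#' Despike a complex sinogram plane
#'
#' Moving-median outlier detection along the shift axis (column-wise: one
#' column per projection): a point is an outlier when its magnitude is more
#' than three local scaled median absolute deviations (scaled MAD = 1.4826
#' x MAD) away from the local median within a centred three-element moving
#' window (at the column ends the window is the three nearest elements, so
#' endpoint bins remain flaggable). The test operates on complex
#' magnitudes (phase-robust, so the mask is invariant to a global complex
#' rescaling). Degenerate windows with MAD = 0 never flag. Outliers are
#' replaced componentwise (real and imaginary) by the median of the
#' non-outlier members of their window; an all-flagged window falls back
#' to the full-window median. Bins marked invalid (e.g. filled by the
#' console's empty-bin interpolation, which duplicates neighbours) can be
#' excluded from the windows via `valid`.
#'
#' @param plane complex matrix (shift bins x projections).
#' @param valid optional logical matrix; FALSE entries are skipped (never
#'   flagged, never used in a window).
#' @return list with `clean` (complex matrix) and `mask` (logical matrix).
#' @export
despike <- function(plane, valid = NULL) {
  if (length(plane) == 0L) stop("despike: empty input")
  if (is.null(dim(plane))) plane <- matrix(plane, ncol = 1L)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(plane), ncol(plane))
  mask <- matrix(FALSE, nrow(plane), ncol(plane))
  clean <- plane
  for (k in seq_len(ncol(plane))) {
    idx <- which(valid[, k])
    if (length(idx) < 3L) next
    col <- plane[idx, k]
    f <- .movOutlier3(Mod(col))$flag
    mask[idx, k] <- f
    if (any(f)) {
      n <- length(idx)
      for (j in which(f)) {
        c0 <- min(max(j, 2L), n - 1L)
        w <- (c0 - 1L):(c0 + 1L)
        good <- w[!f[w]]
        if (!length(good)) good <- w
        clean[idx[j], k] <- complex(real = median(Re(col[good])),
                                    imaginary = median(Im(col[good])))
      }
    }
  }
  list(clean = clean, mask = mask)
}

#' Despike a harmonic plane of a sinogram in place
#'
#' Runs [despike()] on the chosen harmonic plane, stores the cleaned plane
#' back, and records the outlier mask in the sinogram's `outlierMask` slot
#' for downstream weighting.
#'
#' @param sinogram a [Sinogram-class].
#' @param harmonic harmonic number (default 3, the one reconstructed).
#' @return the cleaned [Sinogram-class].
#' @export
despikeSinogram <- function(sinogram, harmonic = 3) {
  stopifnot(is(sinogram, "Sinogram"))
  key <- paste0("h", harmonic)
  res <- despike(sinogram@data[, , key], valid = !sinogram@interpolated)
  sinogram@data[, , key] <- res$clean
  sinogram@outlierMask <- res$mask
  sinogram
}

#' Standard sinogram preprocessing
#'
#' The cleaning chain applied before reconstruction: despiking of the
#' reconstructed harmonic first (a transient landing in the endpoint bins
#' would otherwise corrupt the baseline anchors), then complex linear
#' baseline subtraction per projection.
#'
#' @param sinogram a [Sinogram-class].
#' @param harmonic harmonic to despike (default 3).
#' @return cleaned [Sinogram-class].
#' @export
preprocessSinogram <- function(sinogram, harmonic = 3) {
  subtractBaselineSinogram(despikeSinogram(sinogram, harmonic = harmonic))
}
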