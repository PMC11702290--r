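# Ground-truth phantom generators: capillary line pairs, point-source
# dilution series, and the large 'G' FOV glyph. All rasterization is
# anti-aliased (area-weighted edge pixels) so total mass converges fast in
# pixel pitch; all generators are deterministic.

.gridCenters <- function(n, pitch) (seq_len(n) - (n + 1) / 2) * pitch

.emptyGrid <- function(extentMm, pitch) {
  n <- as.integer(ceiling(extentMm / pitch))
  matrix(0, n, n)
}

# exact fractional overlap of square pixels with an axis-aligned rectangle
.rectCoverage <- function(xc, yc, pitch, x0, x1, y0, y1) {
  ox <- pmax(0, pmin(x1, xc + pitch / 2) - pmax(x0, xc - pitch / 2)) / pitch
  oy <- pmax(0, pmin(y1, yc + pitch / 2) - pmax(y0, yc - pitch / 2)) / pitch
  outer(ox, oy)
}

# supersampled fractional coverage for an arbitrary indicator function
.supersampleCoverage <- function(xc, yc, pitch, inside, ss = 8L) {
  offs <- ((seq_len(ss) - 0.5) / ss - 0.5) * pitch
  cov <- matrix(0, length(xc), length(yc))
  for (dx in offs) {
    xs <- xc + dx
    for (dy in offs) {
      cov <- cov + inside(xs, yc + dy)
    }
  }
  cov / ss^2
}

.phantom <- function(grid, pitch, depth) {
  n <- dim(grid)
  new("PhantomImage", grid = grid, pixelPitch = pitch, depth = depth,
      origin = c((n[1L] + 1) / 2, (n[2L] + 1) / 2))
}

#' Capillary line-pair resolution phantom
#'
#' Two parallel tubes (2D projections: filled rectangles) centred on the
#' isocenter, running along y, with their inner surfaces separated by
#' `separationMm` along x; the center-to-center distance is therefore
#' separation + diameter. Anti-aliased rectangle rasterization makes the
#' total iron mass analytic-exact up to clipping.
#'
#' @param separationMm inner-surface separation, mm (>= 0).
#' @param tubeDiameterMm tube diameter, mm (default 2.5).
#' @param tubeLengthMm tube length, mm (default 50).
#' @param concentration mg Fe / mL (default 0.5).
#' @param pixelPitch mm; must be at most half the tube diameter.
#' @param extentMm grid extent, mm (default 74, a zoomed resolution FOV).
#' @param depthMm slab depth, mm; defaults to the tube diameter so tube
#'   volumes (and masses) are physical.
#' @return a [PhantomImage-class].
#' @examples
#' ph <- makeLinePair(5)              # center-to-center 7.5 mm
#' ironMass(ph) * 1e6                 # ~2 x 156 ug Fe
#' @export
makeLinePair <- function(separationMm, tubeDiameterMm = 2.5, tubeLengthMm = 50,
                         concentration = 0.5, pixelPitch = 0.5,
                         extentMm = 74, depthMm = tubeDiameterMm) {
  if (separationMm < 0) stop("makeLinePair: separation must be >= 0")
  if (tubeDiameterMm <= 0) stop("makeLinePair: diameter must be > 0")
  if (pixelPitch > tubeDiameterMm / 2)
    stop("makeLinePair: pixelPitch > diameter/2 under-resolves the phantom")
  grid <- .emptyGrid(extentMm, pixelPitch)
  xc <- .gridCenters(nrow(grid), pixelPitch)
  yc <- .gridCenters(ncol(grid), pixelPitch)
  s <- separationMm / 2
  cov <- .rectCoverage(xc, yc, pixelPitch, s, s + tubeDiameterMm,
                       -tubeLengthMm / 2, tubeLengthMm / 2) +
         .rectCoverage(xc, yc, pixelPitch, -s - tubeDiameterMm, -s,
                       -tubeLengthMm / 2, tubeLengthMm / 2)
  .phantom(grid + concentration * pmin(cov, 1), pixelPitch, depthMm)
}

#' Point-source phantom
#'
#' A small disc at a stated position whose integrated iron mass equals
#' exactly `volumeUl * concentration` (the rasterized coverage is
#' renormalized to the analytic volume, so a dilution series is exactly
#' linear in concentration). The disc radius follows from the pipetted
#' volume and the slab depth: `r = sqrt(volume / (pi * depth))`.
#'
#' @param volumeUl pipetted volume, microlitres (1 uL = 1 mm^3).
#' @param concentration mg Fe / mL.
#' @param pixelPitch mm.
#' @param extentMm grid extent, mm.
#' @param depthMm sample height, mm.
#' @param centerMm length-2 position of the disc center, mm.
#' @return a [PhantomImage-class].
#' @examples
#' ironMass(makePointSource(20, 6)) * 1e6       # 120 ug Fe
#' ironMass(makePointSource(20, 0.0156)) * 1e9  # 312 ng Fe
#' @export
makePointSource <- function(volumeUl = 20, concentration = 6, pixelPitch = 1,
                            extentMm = 181, depthMm = 5, centerMm = c(0, 0)) {
  if (volumeUl <= 0) stop("makePointSource: volume must be > 0")
  grid <- .emptyGrid(extentMm, pixelPitch)
  if (concentration == 0) return(.phantom(grid, pixelPitch, depthMm))
  r <- sqrt(volumeUl / (pi * depthMm))
  xc <- .gridCenters(nrow(grid), pixelPitch)
  yc <- .gridCenters(ncol(grid), pixelPitch)
  inside <- function(xs, ys) {
    dx2 <- (xs - centerMm[1L])^2
    outer(dx2, (ys - centerMm[2L])^2, "+") <= r^2
  }
  cov <- .supersampleCoverage(xc, yc, pixelPitch, inside, ss = 16L)
  target <- volumeUl / (pixelPitch^2 * depthMm)  # coverage sum giving exact volume
  if (sum(cov) <= 0) stop("makePointSource: disc unresolved at this pitch/extent")
  cov <- cov * (target / sum(cov))
  .phantom(concentration * cov, pixelPitch, depthMm)
}

#' 'G'-shaped field-of-view phantom
#'
#' Open-ring glyph: an annulus of centerline diameter `circleDiameterMm`
#' and radial width `lineWidthMm`, with an angular gap on the +x side, plus
#' the G's horizontal crossbar reaching inward from the ring toward the
#' center at y = 0. The gap angle and bar length are free parameters of the
#' glyph (only ring diameter and line width are metrologically relevant:
#' the known 136 mm centerline diameter calibrates the FOV).
#'
#' @param circleDiameterMm ring centerline diameter, mm (default 136).
#' @param lineWidthMm glyph line width, mm (default 4); must be smaller
#'   than the diameter.
#' @param concentration mg Fe / mL (default 0.0625, a blood-pool level).
#' @param pixelPitch mm.
#' @param extentMm grid extent, mm.
#' @param gapDeg full angular extent of the ring opening, degrees,
#'   centred on +25 deg.
#' @param barLengthMm crossbar length, mm.
#' @param depthMm slab depth, mm.
#' @return a [PhantomImage-class].
#' @export
makeGPhantom <- function(circleDiameterMm = 136, lineWidthMm = 4,
                         concentration = 0.0625, pixelPitch = 1,
                         extentMm = 190, gapDeg = 50, barLengthMm = 30,
                         depthMm = lineWidthMm) {
  if (lineWidthMm >= circleDiameterMm)
    stop("makeGPhantom: line width must be smaller than the ring diameter")
  R <- circleDiameterMm / 2
  w <- lineWidthMm / 2
  gapLo <- (25 - gapDeg / 2) * pi / 180
  gapHi <- (25 + gapDeg / 2) * pi / 180
  grid <- .emptyGrid(extentMm, pixelPitch)
  xc <- .gridCenters(nrow(grid), pixelPitch)
  yc <- .gridCenters(ncol(grid), pixelPitch)
  inside <- function(xs, ys) {
    nx <- length(xs); ny <- length(ys)
    X <- matrix(xs, nx, ny)
    Y <- matrix(ys, nx, ny, byrow = TRUE)
    rr <- sqrt(X^2 + Y^2)
    ang <- atan2(Y, X)
    ring <- abs(rr - R) <= w & !(ang > gapLo & ang < gapHi)
    bar <- X >= (R - barLengthMm) & X <= (R + w) & abs(Y) <= w
    ring | bar
  }
  cov <- .supersampleCoverage(xc, yc, pixelPitch, inside, ss = 8L)
  .phantom(concentration * cov, pixelPitch, depthMm)
}

#' Dilution series of point-source phantoms
#'
#' Geometric series of `nSamples` concentrations from `startConcentration`
#' down to `endConcentration` inclusive (ratio `(end/start)^(1/(n-1))`),
#' each pipetted as a point source of `volumeUl`. Returns the phantoms plus
#' their analytic iron masses. The defaults reproduce an 8-sample series
#' from 6 mg/mL down to 15.6 ug/mL, i.e. 120 ug down to 312 ng of iron in
#' 20 uL.
#'
#' @param volumeUl sample volume per phantom, uL.
#' @param startConcentration mg/mL, largest.
#' @param endConcentration mg/mL, smallest (> 0, < start).
#' @param nSamples number of samples (>= 2).
#' @param ... passed to [makePointSource()] (pitch, extent, depth, center).
#' @return list with elements `phantoms` (list of [PhantomImage-class]),
#'   `concentrations` (mg/mL), and `massesG` (analytic iron mass, g).
#' @export
dilutionSeries <- function(volumeUl = 20, startConcentration = 6,
                           endConcentration = 0.0156, nSamples = 8, ...) {
  if (!(startConcentration > endConcentration && endConcentration > 0))
    stop("dilutionSeries: need start > end > 0")
  if (nSamples < 2) stop("dilutionSeries: need at least 2 samples")
  conc <- exp(seq(log(startConcentration), log(endConcentration),
                  length.out = nSamples))
  phantoms <- lapply(conc, function(cc) makePointSource(volumeUl, cc, ...))
  list(phantoms = phantoms,
       concentrations = conc,
       massesG = volumeUl * conc * 1e-3 * 1e-3)  # uL * mg/mL = ug -> g
}
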