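---
title: "Simulating and reconstructing field-free-line MPI brain images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and reconstructing field-free-line MPI brain images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fflmpi)
```

# The imaging physics being modelled

Magnetic particle imaging (MPI) maps the distribution of a
superparamagnetic iron oxide nanoparticle (SPION) tracer through its
nonlinear magnetization. A mechanically rotated pair of permanent magnets
creates a field-free line (FFL): a line in space where the selection
gradient vanishes. Only tracer near the FFL responds to the sinusoidal
drive field; everything else is magnetically saturated. A slow, roughly
triangular "shift" field translates the FFL across the head, so each
half-period of the shift waveform records one 1D projection of the tracer
distribution, and the rotating gantry supplies projections over 180
degrees — exactly the data geometry of computed tomography, with the FFL
playing the role of the X-ray beam.

`fflmpi` implements this chain at desk scale: tracer physics, read-out
simulation, sinogram formation and cleaning, two tomographic
reconstructions, and the metrology used to validate such a scanner
(resolution from capillary pairs, detection limit from a dilution series,
FOV calibration from a ring phantom), plus the closed-form engineering
calculators for the scanner's coils, gearing and dosimetry.

## Tracer model

The equilibrium magnetization of a SPION in field $H$ is the Langevin
function $L(\xi) = \coth\xi - 1/\xi$ with $\xi = \beta H$. The package
deliberately characterizes a particle by a single steepness $\beta$
(1/T) plus an arbitrary per-gram signal scale, because the measurable
quantity this scanner class reports is the *third-harmonic offset-field
kernel*: sweep a static offset field, record the magnitude of the third
drive harmonic, and read off its full width at half maximum. For a
Synomag-D-like tracer this FWHM is about 6 mT at a 5.8 mT drive.
`calibrateBeta()` inverts that measurement by bracketed root finding on
the monotone map $\beta \mapsto$ FWHM:

```{r}
spion <- spionModel()          # beta calibrated to a 6 mT kernel at 5.8 mT
spion
measureKernelFwhm(spion@beta, 5.8)
```

Relaxation dynamics are omitted: at a 2.7 Hz FFL sweep, microsecond-scale
Néel/Brownian relaxation does not influence the spatial response. The
kernel is applied isotropically in-plane; on hardware only the
through-plane kernel is measured, so this is an explicit assumption of
the simulator.

The received signal is the EMF induced by $dM/dt$ (Faraday induction),
which is why `harmonicResponse()` differentiates the magnetization
waveform (a circular per-sample difference, matching the digitizer) and
reads complex amplitudes at harmonics 2–9 of the drive. Two properties
anchor the tests: at zero offset all even harmonics vanish (odd symmetry
of $L$), and deep in saturation every harmonic dies. The real part of the
phase-aligned third-harmonic kernel has a positive main lobe flanked by
roughly −34% sidelobes — a fact that shapes several behaviours discussed
below. With the 1.13 T/m in-plane gradient, the 6 mT kernel corresponds
to about 5.3 mm FWHM in space, which sets the hardware-level resolution
scale before any deconvolution.

## Acquisition timing and sinogram formation

The drive period is exactly 38 samples at 1 MS/s ($f_d = 10^6/38 \approx
26.3$ kHz), so every period is digitized identically. A read-out (RO) is
35 contiguous drive periods (1.33 ms, 1330 samples); 132 ROs form one
projection; 27 projections cover a 180° sweep in 5 s at 6 RPM; the shift
triangle runs at 2.7 Hz so each projection is one monotone half-period.
The ~5% slack between 132 × 1.33 ms and the 185 ms projection slot is
treated as dead time split evenly across the projection boundaries (the
choice is ours; the timing chain only states the totals).

`simulateImage()` computes, per RO, the mean gantry angle and mean shift
field from this timing model, then sums pixel mass × harmonic kernel at
each pixel's offset field `G·d + Hs`. The kernel is evaluated through a
precomputed offset-field lookup table ("fast kernel mode", 0.05 mT step,
linear interpolation); `simulateReadoutTimedomain()` retains the
brute-force path — synthesize 1330 samples, difference, FFT, read bin
35·n — as the independent oracle, and the two agree to machine precision
for a static offset because the magnetization is exactly periodic over 38
samples. The binning step mirrors the console: 132 uniform shift bins
spanning ±peak, complex averaging within a bin, linear interpolation of
empty bins (flagged in the container). With a rounded shift triangle
(default corner rounding 2% of the period, cosine-blended so value and
slope stay continuous) the waveform never quite reaches ±peak, so the
outermost bins are always interpolation-filled — a deliberate replica of
corner-dwell distortion.

Noise is additive complex white Gaussian per harmonic per RO
(receiver-dominated). Transient spikes — on hardware they arise in the
shift system, plausibly from arcing — are injected *additively* on the
third harmonic: amplitude = `spikeFactor` × the plane's RMS magnitude,
uniform random phase. We model them additively rather than
multiplicatively because an electrical transient couples into the receive
chain regardless of the particle signal; a multiplicative spike would
vanish exactly in the background regions where such spikes are actually
observed.

## Sinogram cleaning

Two operations, in this order:

1. **Despiking.** A bin is an outlier when its magnitude deviates from
   the local median by more than three scaled MADs (1.4826 × MAD) within
   a three-element moving window along the shift axis. Boundary bins use
   the three *nearest* elements (a truncated two-element window can never
   flag anything, which would make endpoint spikes invisible), and
   interpolation-filled bins are excluded from windows (they duplicate a
   neighbour, which would make a spike its own window median). Flagged
   bins are replaced by the componentwise median of their non-flagged
   window neighbours; MAD = 0 windows never flag. Magnitudes are used
   because they are invariant to the global phase of the receive chain.
2. **Baseline subtraction.** Per projection, the complex line through the
   mean of the first two and the mean of the last two bins is subtracted
   — the assumption that there is no tracer at the FOV perimeter. The
   operation is idempotent and exactly nulls the endpoint means.

Despiking comes first because a spike landing in the endpoint bins would
corrupt the baseline anchors (and, once anchored to zero, erase itself).

Known limitations of the three-element MAD rule, measured on simulations:
on pure complex-Gaussian noise it flags ~11% of points (a 3-element MAD
is an extremely noisy scale estimate), so on noisy data it behaves as an
aggressive median smoother of the noise floor rather than a surgical
spike remover — harmless, since replacement is the local median.
Conversely it can false-flag sharp *signal* structure: the bin at a
near-symmetric profile peak, and the cusp-like nulls that appear in
magnitude profiles where the oscillatory third-harmonic kernel crosses
zero, especially at coarse shift-bin sampling. Adjacent spike pairs are
structurally undetectable (both spikes dominate each other's window), so
at a 2% spike rate recall is capped near 96%. The packaged property test
therefore uses the regime the rule is designed for — an extended smooth
tracer distribution at the full 132-bin sampling, where every transient
exceeds the local level — and measures ≥95% recall at <1% false masks.

## Reconstruction

Both algorithms consume the third-harmonic plane, whose symmetric
sensitivity profile makes it valid projection data in 2D. The complex
plane is first rotated by a single global phase so the
signal-energy-weighted mean phase is zero, and the real part is used
(taking magnitudes instead would rectify the noise floor).

* **Inverse Radon** (`inverseRadonRecon()`): Ram-Lak-filtered
  back-projection with linear interpolation over the measured per-
  projection mean angles, shift mapped to line offset by `r = -s/G`,
  cropped to the FOV disc. The filter is exposed as a flag; the ramp is
  the conventional choice for an unapodized "simple inverse Radon".
* **Forward-model iterative** (`iterativeReconSinogram()`): each
  sinogram bin's row in a sparse operator is the known FFL line
  (measured angle, measured shift) convolved perpendicular-to-line with
  a Gaussian of standard deviation 7 mm — the scanner-class
  approximation of the native point spread — truncated at 4σ. The
  system is solved as the normal equations with Jacobi-preconditioned
  conjugate gradients, zero start, and *exactly 15 iterations*: the
  truncation index is the regularization, trading sharpness against
  ringing. No explicit regularization term is added. (Whether the
  original solver symmetrized differently is unknowable from outside;
  the normal-equations form is the standard reading of applying a CG
  solver to a nonsymmetric system.) A technical note: the
  normal-equation residual of PCG is not mathematically guaranteed to
  decrease at every step; on the well-conditioned systems used in the
  unit tests it is monotone through the truncation index, and that is
  what the tests assert.

Post-reconstruction smoothing is an isotropic Gaussian
(σ = FWHM/2.3548, separable, sum-preserving): 1.5 mm FWHM for resolution
studies (well below the expected resolution), 6 mm for detection-limit
studies (matched to the practical resolution).

The image grid is 132×132 pixels over the configured FOV with pixel
centers at half-integer offsets and the isocenter at the grid center;
angles are counter-clockwise from +x, and at gantry angle 0 the FFL lies
along the x axis. The iterative solve in the packaged resolution
experiment uses a 96×96 grid by default (still ~4 pixels per kernel
standard deviation; the Gaussian forward operator is dense enough that
the 132 grid roughly doubles memory and build time, and the resolved
separations it yields are the same).

## Validation metrology

`contrastMetric()` implements the two-peak contrast
$C = 1 - S_\min / \tfrac12(S_{\max,L} + S_{\max,R})$ with the two most
*prominent* local maxima (topographic prominence), because reconstructed
profiles carry ringing sidelobes that raw-height peak picking would
confuse with tubes. C > 0.5 is "resolved". The statistic is evaluated on
the signed (phase-aligned real) central profile, not its magnitude:
rectified profiles turn the kernel's negative sidelobes into spurious
peaks, and for an unresolved pair the prominence picker would then pair
the merged blob with a sidelobe across a zero crossing and report
near-perfect contrast. The signed profile keeps the geometry honest, at
the price that C exceeds 1 when the inter-peak valley undershoots zero —
which it does, strongly, for well-separated tubes, precisely because of
the −34% kernel sidelobes superposing between them.

That last effect has a consequence worth stating plainly: in a noiseless
simulation the inverse-Radon contrast at 8–9 mm separations is inflated
past 1 by sidelobe undershoot, while the iterative reconstruction —
deconvolving with a 7 mm-std kernel roughly 3× broader than the
simulation's true ~2.3 mm-std point spread — leaves a small positive
valley at 8 mm. So the hardware observation that the iterative contrast
dominates at *every* separation does not reproduce in the saturated
(fully resolved) regime of this idealized surrogate; the deconvolution
gain is unambiguous in the regime that defines the resolution numbers
(5–7 mm), and both headline results do reproduce: iterative resolved at
5 mm, inverse Radon at 6 mm (hardware: 7 mm, with the surrogate expected
to do no worse since its in-plane kernel is, by assumption, the narrow
through-plane one).

`detectionLimit()` fits peak signal against iron mass by ordinary least
squares and solves the fitted line against k·σ of an empty-bore image
(k = 1, 5), intercept included. The measured LODs of the physical
scanner depend on its shift-amplifier noise floor and are not simulation
targets; the package reproduces the procedure and its scaling laws
(LOD ∝ 1/slope; R² ≥ 0.9999 on noiseless series — exact because point
sources are mass-renormalized at rasterization). `fovCalibration()`
scales a known feature extent (the 136 mm ring centerline of the 'G'
glyph, measured between subpixel-refined profile peaks) to the full
grid.

## Phantoms and the synthetic-data generator

Phantoms are 2D concentration maps (mg Fe/mL) with an explicit slab
depth so masses are physical: capillary pairs (2.5 mm tubes, 0.5 mg/mL,
inner-surface separations 5–9 mm, imaged in a zoomed 74 mm FOV),
20 µL point sources for the dilution series (6 mg/mL down to
15.6 µg/mL — a geometric series between the stated endpoints, since
those endpoints are not an exact factor-2 chain — giving 120 µg down to
312 ng Fe), and the 136 mm 'G' ring with 4 mm lines at 0.0625 mg/mL, the
blood-pool concentration for a 5 mg/kg dose in 65 mL/kg of blood. The
glyph's gap angle and bar length are free parameters (only the ring
diameter and line width are metrologically constrained); defaults are a
50° gap and a 30 mm bar. Rasterization is anti-aliased (exact pixel
overlap for rectangles, supersampled coverage for curved shapes), which
is why masses converge to analytic values at the per-mille level and
halving the pitch moves them by <0.5%.

What the generator does *not* emulate: receive-chain spectra and
filtering, drive-field inhomogeneity, gantry angle jitter, relaxation
blurring, an anisotropic in-plane kernel, and the non-Gaussian background
structure that dominates the hardware's empty-bore images. Passing tests
therefore validate the computational chain and its internal consistency,
not the hardware's noise-limited figures (its µg-level detection limits,
its measured 181 mm FOV).

## Numerical choices and problem sizes

Defaults chosen once: kernel lookup step 0.05 mT (≪ the 6 mT kernel);
shift-corner rounding 2% of the period; spike factor 20× plane RMS;
phantom pitch 0.5 mm for line pairs (5 pixels per tube diameter);
test problem sizes of 16×16–48×48 grids with ray sampling dense enough
that the 15-iteration solver is in its converged regime for the oracle
comparisons (the deconvolution oracle needs a near-complete system; a
deliberately ill-posed one is exercised separately through the resolution
study). The acceptance computation simulates five line-pair acquisitions
at full 132 × 27 sinogram size and reconstructs each with both
algorithms; it completes in well under a minute on one CPU.

Degenerate inputs are defined, not accidental: zero-concentration
phantoms simulate to noise-only read-outs; `nIter = 0` returns the zero
image; `fwhm = 0` smoothing is the identity; an exact triangle
(`roundingFraction = 0`) is permitted; MAD = 0 windows never flag;
profiles with fewer than two maxima raise an "unresolved" error distinct
from C ≤ 0.5.
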