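# fflmpi

Desk-scale simulation and reconstruction for a mechanically rotated
field-free-line (FFL) magnetic particle imaging (MPI) scanner at human
brain scale.

MPI images a superparamagnetic iron oxide (SPION) tracer through its
nonlinear magnetization M = M₀·L(βH), L(ξ) = coth ξ − 1/ξ. A permanent-
magnet FFL (1.13 T/m in-plane gradient) localizes the response to a line;
a 26.3 kHz drive field generates harmonics of the tracer near the line; a
2.7 Hz triangular shift field sweeps the line across the head to form 1D
projections; a gantry rotating at 6 RPM supplies 27 projections per 180°
in 5 s. The third-harmonic sinogram S(s, θ) is cleaned (complex linear
baseline subtraction, moving-median scaled-MAD despiking) and
reconstructed two ways:

* **inverse Radon** — Ram-Lak filtered back-projection of the
  phase-aligned third harmonic;
* **forward-model iterative** — a sparse operator whose rows are the
  known FFL lines convolved with a 7 mm-std Gaussian kernel, inverted by
  exactly 15 Jacobi-preconditioned conjugate-gradient iterations on the
  normal equations (truncation is the regularization).

Resolution is scored with the two-peak contrast
C = 1 − S_min / (0.5·(S_max,L + S_max,R)), resolved when C > 0.5;
sensitivity with a dilution-series regression against the empty-bore
noise floor (LOD at 5σ); the field of view by calibrating against the
136 mm ring of a 'G' phantom. Closed-form engineering calculators
(shift-coil heat load, parallel thermal resistance, gear trains, sweep
timing, tracer dosimetry) round out the toolkit. The package is aimed at
MPI instrument builders and image-reconstruction researchers who want a
reproducible software twin of this scanner class.

## Worked example

Simulate a 7 mm capillary-pair phantom at the scanner's zoomed resolution
operating point (74 mm FOV, 5.8 mT drive) and reconstruct it:

```r
library(fflmpi)

scannerConfig()
#> ScannerConfig
#>   gradient (in-plane): 1.13 T/m   drive: 5.8 mT @ 26.316 kHz
#>   shift: 102.3 mT @ 2.7 Hz  ->  FOV 181 mm
#>   132 ROs x 27 projections, 35 periods/RO, gantry 6 RPM, 180 deg sweep

spion <- spionModel()   # Langevin steepness calibrated to the 6 mT h3 kernel
spion
#> SpionModel 'Synomag-D-like': beta = 330.93 /T, signalScale = 1 /gFe (h3 kernel FWHM 6 mT @ 5.8 mT drive)

ph <- makeLinePair(7)           # two 2.5 mm tubes, inner surfaces 7 mm apart
ro <- simulateImage(ph, resolutionConfig(), spion)
sg <- preprocessSinogram(binToSinogram(ro))
sg
#> Sinogram: 132 shift bins x 27 projections x 8 harmonics
#>   shift -41.49..41.49 mT, angles 3.33..176.67 deg, 162 interpolated bins, 36 masked

im <- inverseRadonRecon(sg)     # FBP + 1.5 mm FWHM smoothing
pr <- centralProfile(im)
contrastMetric(pr$values, pr$positions)$C
#> [1] 1.08
```

C = 1.08 > 0.5: the 7 mm pair is resolved (the valley undershoots zero —
a signature of the third-harmonic kernel's negative sidelobes — so the
contrast exceeds 1). The tube peaks sit at ±4.8 mm, the expected
(7 + 2.5)/2 = 4.75 mm center offset. The engineering calculators print
their numbers directly:

```r
triangleHeatLoad(250, c(0.310, 0.310, 0.399, 0.399)) / 1e3   # kW
#> [1] 29.54167
voxelIronMass(5, 65, 0.05, 6)$massNg   # gray-matter iron per 6 mm voxel
#> [1] 830.7692
```

## Layout

* `R/` — S4 classes (`ScannerConfig`, `SpionModel`, `PhantomImage`,
  `ReadoutSet`, `Sinogram`, `ReconImage`, `SystemMatrix`) and the module
  functions: tracer/field physics, phantom generators, acquisition
  simulation, sinogram cleaning, both reconstructions, metrology,
  engineering calculators, experiment drivers, plain-text I/O.
* `vignettes/ffl-mpi-simulation.Rmd` — the model, its assumptions,
  parameter choices, numerical details and known limitations.
* `tests/testthat/` — unit, property and end-to-end acceptance tests.
* `inst/extdata/default-config.yaml` — the packaged scanner operating
  point.
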