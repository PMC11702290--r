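# Closed-form engineering and dosimetry calculators for the scanner:
# shift-coil heat load, parallel thermal resistance, gantry gearing,
# sweep timing, Joule temperature rise, and the tracer dose -> iron mass
# per voxel chain. All pure functions with units checked at the boundary.

#' Resistive heat load of a triangle-wave current drive
#'
#' A triangle wave of peak current I has RMS I/sqrt(3), so at 100% duty
#' the dissipated power in a bank of series-driven coils is
#' `P = I^2 / 3 * sum(R)`. With the measured shift-coil DC resistances
#' (0.310, 0.310, 0.399, 0.399 ohm) at 250 A peak this is 29.5 kW.
#'
#' @param iPeakA peak current, A (>= 0).
#' @param resistancesOhm DC resistance per coil, ohm (> 0).
#' @return power, W.
#' @examples
#' triangleHeatLoad(250, c(0.310, 0.310, 0.399, 0.399)) / 1e3  # 29.5 kW
#' @export
triangleHeatLoad <- function(iPeakA, resistancesOhm) {
  if (iPeakA < 0) stop("triangleHeatLoad: current must be >= 0")
  if (!length(resistancesOhm) || any(resistancesOhm <= 0))
    stop("triangleHeatLoad: resistances must be positive")
  (iPeakA^2 / 3) * sum(resistancesOhm)
}

#' Net thermal resistance of parallel cooling branches
#'
#' Reciprocal of the sum of reciprocals: four 60 mK/W modules in parallel
#' give 15 mK/W.
#'
#' @param branchResistances K/W per branch (> 0, non-empty).
#' @return K/W.
#' @examples
#' parallelThermalResistance(rep(0.060, 4))  # 0.015
#' @export
parallelThermalResistance <- function(branchResistances) {
  if (!length(branchResistances)) stop("parallelThermalResistance: empty branch list")
  if (any(branchResistances <= 0)) stop("parallelThermalResistance: branches must be positive")
  1 / sum(1 / branchResistances)
}

#' Output speed of a gear train
#'
#' Product of the input speed and the stage ratios: a 580 RPM motor
#' through a 1:10 worm gear and 16:155 wheel gearing turns the gantry at
#' very nearly 6 RPM.
#'
#' @param inputRpm input speed, rev/min.
#' @param ratios dimensionless stage ratios (> 0); empty = direct drive.
#' @return output speed, rev/min.
#' @examples
#' gearTrainSpeed(580, c(1 / 10, 16 / 155))  # ~5.99 RPM
#' @export
gearTrainSpeed <- function(inputRpm, ratios = numeric()) {
  if (length(ratios) && any(ratios <= 0)) stop("gearTrainSpeed: ratios must be positive")
  inputRpm * prod(ratios)
}

#' Gantry sweep time
#'
#' Time to sweep the stated angle at the stated rotation speed:
#' `(degrees / 360) * 60 / rpm`. 180 degrees at 6 RPM is 5 s.
#'
#' @param gantryRpm rev/min (> 0).
#' @param degrees sweep angle, degrees (>= 0).
#' @return time, s.
#' @examples
#' sweepTime(6, 180)  # 5 s
#' @export
sweepTime <- function(gantryRpm, degrees) {
  if (gantryRpm <= 0) stop("sweepTime: rpm must be > 0")
  (degrees / 360) * 60 / gantryRpm
}

#' Iron mass per voxel from an intravascular tracer dose
#'
#' The dose (mg Fe per kg body mass) distributes through the blood volume
#' (mL per kg body mass), giving a blood iron concentration; scaled by the
#' tissue blood volume fraction and the voxel volume this yields the iron
#' mass per voxel. Computed without intermediate rounding: 5 mg/kg over
#' 65 mL/kg in 5%-blood gray matter and a 6 mm voxel (216 uL) gives
#' 830 ng Fe.
#'
#' @param doseMgPerKg tracer dose, mg Fe / kg body mass.
#' @param bloodVolumePerMassMlPerKg blood volume per body mass, mL/kg.
#' @param tissueBloodFraction blood volume fraction of the tissue, 0..1.
#' @param voxelEdgeMm isotropic voxel edge, mm.
#' @return list with `massNg` (ng Fe per voxel), `bloodConcMgPerMl`
#'   (mg Fe / mL blood), `tissueConcMgPerMl` and `voxelVolumeUl`.
#' @examples
#' voxelIronMass(5, 65, 0.05, 6)$massNg  # ~830 ng
#' @export
voxelIronMass <- function(doseMgPerKg, bloodVolumePerMassMlPerKg,
                          tissueBloodFraction, voxelEdgeMm) {
  if (any(c(doseMgPerKg, bloodVolumePerMassMlPerKg, voxelEdgeMm) <= 0))
    stop("voxelIronMass: dose, blood volume and voxel edge must be positive")
  if (tissueBloodFraction < 0 || tissueBloodFraction > 1)
    stop("voxelIronMass: blood fraction must be in [0, 1]")
  bloodConc <- doseMgPerKg / bloodVolumePerMassMlPerKg      # mg/mL blood
  tissueConc <- bloodConc * tissueBloodFraction             # mg/mL tissue
  voxelUl <- voxelEdgeMm^3                                  # 1 mm^3 = 1 uL
  massMg <- tissueConc * voxelUl * 1e-3                     # uL -> mL
  list(massNg = massMg * 1e6, bloodConcMgPerMl = bloodConc,
       tissueConcMgPerMl = tissueConc, voxelVolumeUl = voxelUl)
}

#' Joule temperature rise across a thermal resistance
#'
#' `dT = P * Rth`. At the drive coil's typical 1.6 kW and 15 mK/W net
#' cooling resistance this computes 24 K.
#'
#' @param powerW dissipated power, W (>= 0).
#' @param thermalResistanceKPerW K/W (>= 0).
#' @return temperature rise, K.
#' @examples
#' jouleTemperatureRise(1600, 0.015)  # 24 K
#' @export
jouleTemperatureRise <- function(powerW, thermalResistanceKPerW) {
  if (powerW < 0 || thermalResistanceKPerW < 0)
    stop("jouleTemperatureRise: arguments must be nonnegative")
  powerW * thermalResistanceKPerW
}
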