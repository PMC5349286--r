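# Unit physics: ideal-gas molar volume, gas volume <-> moles, outflow
# dilution, concentration -> daily molar flux.

#' Physical constants of the fermenter system
#'
#' Bundles the physical configuration used throughout the pipeline: gas
#' constant, incubation temperature and pressure, daily artificial-saliva
#' outflow and vessel working volume. The defaults are the study system
#' (39 degrees C, 1.013e5 Pa, 626 mL/d infusion into a 900 mL vessel).
#'
#' `molar_volume = "exact"` uses the full-precision ideal-gas value
#' R*T/P (25.619 L/mol at the defaults); `"paper"` forces the rounded
#' 25.6 L/mol so that printed report values can be reproduced bit-for-bit.
#'
#' @param temperature Kelvin. Default 312.15 (39 degrees C).
#' @param pressure Pascal. Default 1.013e5.
#' @param outflow Saliva outflow, L/d. Default 0.626.
#' @param vessel_volume Working volume, mL. Default 900.
#' @param molar_volume `"exact"` or `"paper"` (see Details).
#' @param gas_constant J/(mol K). Fixed at 8.314 by default.
#'
#' @return A list with class `"physical_constants"`.
#' @examples
#' physical_constants()
#' molar_volume(physical_constants(molar_volume = "paper"))
#' @export
physical_constants <- function(temperature = 312.15,
                               pressure = 1.013e5,
                               outflow = 0.626,
                               vessel_volume = 900,
                               molar_volume = c("exact", "paper"),
                               gas_constant = 8.314) {
  molar_volume <- match.arg(molar_volume)
  if (temperature <= 0) abort("`temperature` must be > 0 K")
  if (pressure <= 0) abort("`pressure` must be > 0 Pa")
  if (outflow < 0) abort("`outflow` must be >= 0 L/d")
  if (vessel_volume <= 0) abort("`vessel_volume` must be > 0 mL")
  structure(
    list(
      gas_constant = gas_constant, temperature = temperature,
      pressure = pressure, outflow = outflow,
      vessel_volume = vessel_volume, molar_volume = molar_volume
    ),
    class = "physical_constants"
  )
}

#' Ideal-gas molar volume
#'
#' R*T/P expressed in L/mol. At the study conditions (312.15 K, 1.013e5 Pa)
#' this is 25.619 L/mol, which the study rounds to 25.6; pass constants
#' built with `molar_volume = "paper"` to get the rounded value exactly.
#'
#' @param constants A [physical_constants()] object.
#' @return Molar volume in L/mol.
#' @examples
#' molar_volume(physical_constants()) # 25.619...
#' molar_volume(physical_constants(temperature = 273.15, pressure = 101325))
#' @export
molar_volume <- function(constants = physical_constants()) {
  stopifnot(inherits(constants, "physical_constants"))
  if (identical(constants$molar_volume, "paper")) {
    return(25.6)
  }
  # R*T/P is m^3/mol; x1000 to L/mol
  constants$gas_constant * constants$temperature / constants$pressure * 1000
}

#' Convert a daily gas volume to a daily molar flux
#'
#' @param volume_ml Gas volume, mL/d.
#' @param mol_vol Molar volume, L/mol (e.g. from [molar_volume()]).
#' @return Molar flux, mmol/d. (mL divided by L/mol is mmol.)
#' @examples
#' gas_volume_to_mmol(25600, 25.6) # 1000 mmol
#' @export
gas_volume_to_mmol <- function(volume_ml, mol_vol = molar_volume()) {
  if (any(volume_ml < 0, na.rm = TRUE)) abort("gas volume must be >= 0")
  if (any(mol_vol <= 0)) abort("molar volume must be > 0")
  volume_ml / mol_vol
}

#' Convert a daily molar flux back to a gas volume
#'
#' Inverse of [gas_volume_to_mmol()].
#' @param mmol_d Molar flux, mmol/d.
#' @param mol_vol Molar volume, L/mol.
#' @return Volume, mL/d.
#' @export
gas_mmol_to_volume <- function(mmol_d, mol_vol = molar_volume()) {
  if (any(mmol_d < 0, na.rm = TRUE)) abort("molar flux must be >= 0")
  mmol_d * mol_vol
}

#' Concentration in the outflow to daily molar flux
#'
#' A solute at concentration `conc` (mM) leaving with the daily saliva
#' outflow (`outflow` L/d) corresponds to `conc * outflow` mmol/d.
#'
#' @param conc Concentration, mM.
#' @param outflow Outflow, L/d (default the study's 0.626).
#' @return Flux, mmol/d.
#' @examples
#' concentration_to_daily_flux(65.5) # 41.0 mmol/d
#' @export
concentration_to_daily_flux <- function(conc, outflow = 0.626) {
  if (any(conc < 0, na.rm = TRUE)) abort("concentration must be >= 0")
  if (any(outflow < 0)) abort("outflow must be >= 0")
  conc * outflow
}

#' Hourly dilution rate of the vessel
#'
#' @param infusion Daily infusion, mL/d.
#' @param vessel_volume Working volume, mL.
#' @return Dilution rate, %/h. 626 mL/d in 900 mL gives 2.9 %/h.
#' @examples
#' dilution_rate(626, 900)
#' @export
dilution_rate <- function(infusion, vessel_volume = 900) {
  if (any(vessel_volume <= 0)) abort("vessel volume must be > 0")
  if (any(infusion < 0)) abort("infusion must be >= 0")
  infusion / 24 / vessel_volume * 100
}
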