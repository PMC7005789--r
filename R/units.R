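# Physical constants.  Boltzmann constant in the two energy units the toolkit
# touches: kcal/mol (reporting convention of the field) and kJ/mol (GROMACS
# file convention).
.kB_kcal <- 0.0019872041
.kB_kJ <- 0.0083144621

#' Thermal energy and unit conversions
#'
#' All estimator math inside the package is dimensionless (units of kT).
#' These helpers convert between kT and the conventional reporting units at a
#' given absolute temperature.
#'
#' @param temperature absolute temperature in kelvin (default 300 K).
#' @param x energy value(s) to convert.
#' @return `kT_kcal_per_mol()`/`kT_kJ_per_mol()` return the thermal energy
#'   k_B*T in kcal/mol or kJ/mol; `kcal_to_kT()` and `kT_to_kcal()` convert
#'   energies between kcal/mol and kT.
#' @examples
#' kT_kcal_per_mol(300) # 0.59616 kcal/mol
#' kT_to_kcal(1, 300)
#' @export
kT_kcal_per_mol <- function(temperature = 300) {
  .check_temperature(temperature)
  .kB_kcal * temperature
}

#' @rdname kT_kcal_per_mol
#' @export
kT_kJ_per_mol <- function(temperature = 300) {
  .check_temperature(temperature)
  .kB_kJ * temperature
}

#' @rdname kT_kcal_per_mol
#' @export
kcal_to_kT <- function(x, temperature = 300) x / kT_kcal_per_mol(temperature)

#' @rdname kT_kcal_per_mol
#' @export
kT_to_kcal <- function(x, temperature = 300) x * kT_kcal_per_mol(temperature)

.check_temperature <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    fep_abort("`temperature` must be a single positive number (kelvin)",
              "fepddg_input_error")
  }
  invisible(temperature)
}
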