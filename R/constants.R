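#' Physical constants and unit conversions
#'
#' The package stores activation energies in kJ/mol, pre-exponential
#' factors in min^-1, and temperatures in degrees Celsius at the user
#' interface. All conversions are centralised here.
#'
#' @format `gas_constant` is the molar gas constant R, 8.314 J mol^-1 K^-1.
#' @keywords internal
#' @name constants
NULL

#' @rdname constants
#' @export
gas_constant <- 8.314

#' Convert Celsius to Kelvin
#'
#' Adds 273.15 exactly.
#'
#' @param temperature_C temperature in degrees Celsius.
#' @return temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(temperature_C) {
  stopifnot(is.numeric(temperature_C))
  temperature_C + 273.15
}

# slope coefficient b = Ea / R in Kelvin, for ln k = ln A - b * (1/T);
# Ea in kJ/mol, R in J/(mol K)
ea_to_slope_K <- function(Ea_kJ) Ea_kJ * 1000 / gas_constant

slope_K_to_ea <- function(slope_K) slope_K * gas_constant / 1000
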