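#' Thermal voltage at the recording temperature
#'
#' Returns \eqn{k_B T / e_0} in millivolts. All voltage-dependent expressions
#' in the package (rate laws, Boltzmann conductance curves, equilibrium
#' constants) use this scale factor. The recording temperature is fixed at
#' 296 K, giving \eqn{k_B T / e_0 \approx 25.51} mV.
#'
#' @param temperature_K Absolute temperature in kelvin. Default 296 K.
#' @return Thermal voltage in mV (scalar).
#' @examples
#' thermal_voltage_mV() # ~25.51
#' @export
thermal_voltage_mV <- function(temperature_K = 296) {
  kB <- 1.380649e-23 # J/K
  e0 <- 1.602176634e-19 # C
  1000 * kB * temperature_K / e0
}
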