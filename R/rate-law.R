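#' Voltage-dependent rate law
#'
#' A single-exponential rate law \eqn{k(V) = k(0)\,e^{z V e_0 / k_B T}},
#' the standard description of a voltage-dependent transition rate: `k0` is
#' the rate at 0 mV (s^-1) and `z` the apparent partial charge moved (units of
#' e0). `z` may be negative; closing rates of depolarization-activated
#' channels typically carry negative charge.
#'
#' @param k0 Rate constant at 0 mV, in s^-1. Must be > 0.
#' @param z Apparent partial charge in elementary charges. Must be finite.
#' @return An object of class `rate_law`.
#' @seealso [rate_at_voltage()], [fit_rate_voltage()]
#' @examples
#' rate_at_voltage(rate_law(875.09, -0.13178), 70) # ~609.6 s^-1
#' @export
rate_law <- function(k0, z) {
  stopifnot(is.numeric(k0), length(k0) == 1, is.finite(k0), k0 > 0,
            is.numeric(z), length(z) == 1, is.finite(z))
  structure(list(k0 = as.numeric(k0), z = as.numeric(z)), class = "rate_law")
}

#' @export
print.rate_law <- function(x, ...) {
  cat(sprintf("<rate_law> k(0) = %g s^-1, z = %g e0\n", x$k0, x$z))
  invisible(x)
}

is_rate_law <- function(x) inherits(x, "rate_law")

#' Evaluate a rate law at a voltage
#'
#' Computes \eqn{k(V) = k(0)\,\exp(z V e_0 / k_B T)} with the thermal voltage
#' at 296 K (see [thermal_voltage_mV()]). At `V = 0` the result is exactly
#' `k0`; `z = 0` gives a voltage-independent rate.
#'
#' @param law A [rate_law()]. A bare positive number is accepted and treated
#'   as a fixed (voltage-independent) rate.
#' @param V Membrane potential(s) in mV, depolarization positive.
#' @return Rate(s) in s^-1, same length as `V`.
#' @export
rate_at_voltage <- function(law, V) {
  stopifnot(is.numeric(V), all(is.finite(V)))
  if (is.numeric(law) && length(law) == 1 && law >= 0) {
    return(rep(as.numeric(law), length(V)))
  }
  stopifnot(is_rate_law(law))
  law$k0 * exp(law$z * V / thermal_voltage_mV())
}
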