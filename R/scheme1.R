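#' Star-topology kinetic scheme: one open state, three closed states
#'
#' The minimal model for bursting single-channel activity with fast flicker:
#' a single open state O connected to three closed states by slow
#' (\eqn{\alpha}), medium (\eqn{\beta}) and fast (\eqn{\gamma}) transition
#' pairs. For each pair the `_o` rate opens the channel (C -> O) and the `_c`
#' rate closes it (O -> C). Rates may be fixed values in s^-1 (analysis at a
#' single voltage) or [rate_law()] objects (voltage-dependent analysis).
#'
#' @param alpha_o,alpha_c Slow opening/closing rates (s^-1 or [rate_law()]).
#' @param beta_o,beta_c Medium opening/closing rates.
#' @param gamma_o,gamma_c Fast opening/closing rates.
#' @return An object of class `scheme1_params`.
#' @examples
#' p <- scheme1_params(alpha_o = 1500, alpha_c = 27,
#'                     beta_o = 22500, beta_c = 600,
#'                     gamma_o = 127500, gamma_c = 30000)
#' predict_open_probability(p) # ~0.781
#' @export
scheme1_params <- function(alpha_o, alpha_c, beta_o, beta_c, gamma_o, gamma_c) {
  p <- list(alpha_o = alpha_o, alpha_c = alpha_c,
            beta_o = beta_o, beta_c = beta_c,
            gamma_o = gamma_o, gamma_c = gamma_c)
  # fixed rates of 0 are tolerated (limits such as P_O -> 1); simulation and
  # scheme expansion still require strictly positive rates
  ok <- function(x) is_rate_law(x) ||
    (is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0)
  if (!all(purrr::map_lgl(p, ok))) {
    abort("each rate must be a nonnegative number or a rate_law")
  }
  structure(p, class = "scheme1_params")
}

#' @export
print.scheme1_params <- function(x, ...) {
  cat("<scheme1_params>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is_rate_law(v)) {
      cat(sprintf("  %-8s k(0) = %10.4g s^-1  z = %+.4g e0\n", nm, v$k0, v$z))
    } else {
      cat(sprintf("  %-8s %10.4g s^-1\n", nm, v))
    }
  }
  invisible(x)
}

#' Evaluate the six rates of a star scheme at a voltage
#'
#' @param p A [scheme1_params()].
#' @param V Membrane potential in mV (ignored for fixed rates).
#' @return Named numeric vector of the six rates in s^-1.
#' @export
scheme1_rates_at <- function(p, V = 0) {
  stopifnot(inherits(p, "scheme1_params"))
  purrr::map_dbl(unclass(p), rate_at_voltage, V = V)
}

#' Closed-form open probability of the star scheme
#'
#' At steady state the occupancy ratio of each closed state to the open state
#' is the inverse of its equilibrium constant \eqn{K_i = k_{i,o}/k_{i,c}}
#' (opening over closing rate), so
#' \deqn{P_O = \left[1 + 1/K_s + 1/K_m + 1/K_f\right]^{-1}.}
#' This equals the open-state entry of the stationary distribution of the
#' four-state generator (see [steady_state_occupancy()]), which is used as an
#' independent oracle in the package tests.
#'
#' @param p A [scheme1_params()].
#' @param V Membrane potential(s) in mV; vectorized.
#' @return Open probability in (0, 1], same length as `V`.
#' @export
predict_open_probability <- function(p, V = 0) {
  stopifnot(inherits(p, "scheme1_params"))
  r <- purrr::map(unclass(p), rate_at_voltage, V = V)
  if (any(r$alpha_c == 0 | r$beta_c == 0 | r$gamma_c == 0)) {
    warn("a closing rate is zero; open probability tends to 1")
  }
  Ks <- r$alpha_o / r$alpha_c
  Km <- r$beta_o / r$beta_c
  Kf <- r$gamma_o / r$gamma_c
  1 / (1 + 1 / Ks + 1 / Km + 1 / Kf)
}

#' Equilibrium constants of the star scheme
#'
#' @inheritParams predict_open_probability
#' @return A tibble with columns `transition` (slow/medium/fast) and `K`
#'   (opening rate over closing rate).
#' @export
scheme1_equilibrium_constants <- function(p, V = 0) {
  r <- scheme1_rates_at(p, V)
  tibble::tibble(
    transition = c("slow", "medium", "fast"),
    K = c(r[["alpha_o"]] / r[["alpha_c"]],
          r[["beta_o"]] / r[["beta_c"]],
          r[["gamma_o"]] / r[["gamma_c"]])
  )
}

#' Expand star-scheme parameters into a full gating scheme
#'
#' Builds the four-state [gating_scheme()] (O, C_s, C_m, C_f) at a fixed
#' voltage, for simulation and for the null-space steady-state solver.
#'
#' @inheritParams predict_open_probability
#' @param i_open Open-state amplitude in pA.
#' @param V Voltage in mV at which voltage-dependent rates are frozen.
#' @return A [gating_scheme()].
#' @export
as_gating_scheme <- function(p, i_open = 10, V = 0) {
  r <- scheme1_rates_at(p, V)
  states <- tibble::tibble(
    label = c("O", "Cs", "Cm", "Cf"),
    class = c("open", "closed", "closed", "closed"),
    amplitude = c(i_open, 0, 0, 0)
  )
  rates <- tibble::tibble(
    from = c("Cs", "O", "Cm", "O", "Cf", "O"),
    to = c("O", "Cs", "O", "Cm", "O", "Cf"),
    k0 = unname(r[c("alpha_o", "alpha_c", "beta_o", "beta_c",
                    "gamma_o", "gamma_c")]),
    z = 0
  )
  gating_scheme(states, rates)
}

#' Net charge moved by one transition pair
#'
#' The total gating charge associated with a transition is the difference
#' between the partial charges of its opening and closing rates,
#' \eqn{Z_i = z_{i,o} - z_{i,c}}.
#'
#' @param z_o,z_c Partial charges (e0) of the opening and closing rate.
#' @return \eqn{Z_i} in e0.
#' @examples
#' total_transition_charge(-0.13178, -0.55262) # 0.42084
#' @export
total_transition_charge <- function(z_o, z_c) {
  stopifnot(is.numeric(z_o), is.numeric(z_c),
            all(is.finite(z_o)), all(is.finite(z_c)))
  z_o - z_c
}
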