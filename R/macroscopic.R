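#' Generate a macroscopic voltage-step current family
#'
#' Emulates a whole-patch voltage-step experiment: for each test potential a
#' 150-ms current trace is produced whose steady-state level is
#' \deqn{I(V) = N \, P_O(V) \, g \, (V - V_{rev}) / 1000}
#' (pA, with `g` in pS and voltages in mV), plus white Gaussian noise.
#' `truth` sets the open-probability curve: either a Boltzmann description
#' `list(z = , v_half = )` or a [scheme1_params()] whose rates are
#' [rate_law()]s (open probability from the star-scheme closed form).
#'
#' The default protocol is 20-mV steps from -130 to +130 mV.
#'
#' @param truth `list(z, v_half)` or a [scheme1_params()].
#' @param n_channels Number of channels in the patch (>= 1).
#' @param g Single-channel conductance in pS.
#' @param v_rev Reversal potential in mV.
#' @param voltages Test potentials in mV.
#' @param noise_sigma White noise SD in pA added to every sample.
#' @param step_duration Step length in seconds.
#' @param f_s Sampling rate in Hz for the step traces.
#' @param seed Optional integer seed.
#' @return A tibble with columns `voltage` (mV), `time` (s), `current` (pA)
#'   and attribute `truth_manifest` (list with the generating parameters,
#'   seed, and the noiseless steady-state currents).
#' @seealso [measure_steady_state()], [fit_boltzmann()]
#' @export
generate_macroscopic <- function(truth, n_channels = 100, g = 100, v_rev = 0,
                                 voltages = seq(-130, 130, by = 20),
                                 noise_sigma = 0, step_duration = 0.15,
                                 f_s = 10000, seed = NULL) {
  stopifnot(n_channels >= 1, g > 0, step_duration > 0, f_s > 0)
  restore <- local_seed(seed)
  on.exit(restore())
  po <- open_probability_curve(truth, voltages)
  i_ss <- n_channels * po * g * (voltages - v_rev) / 1000
  n <- floor(step_duration * f_s)
  out <- tidyr::expand_grid(voltage = voltages,
                            time = (seq_len(n) - 0.5) / f_s)
  out$current <- rep(i_ss, each = n) +
    if (noise_sigma > 0) rnorm(nrow(out), sd = noise_sigma) else 0
  attr(out, "truth_manifest") <- list(
    truth = truth, n_channels = n_channels, g = g, v_rev = v_rev,
    voltages = voltages, noise_sigma = noise_sigma, seed = seed,
    steady_state_current = i_ss, open_probability = po
  )
  out
}

# open-probability curve from either a Boltzmann truth or scheme1 rate laws
open_probability_curve <- function(truth, voltages) {
  if (inherits(truth, "scheme1_params")) {
    predict_open_probability(truth, voltages)
  } else if (is.list(truth) && all(c("z", "v_half") %in% names(truth))) {
    boltzmann_po(voltages, truth$z, truth$v_half)
  } else {
    abort("truth must be list(z, v_half) or scheme1_params")
  }
}

# rising Boltzmann: P_O = 1 / (1 + exp(-z (V - V1/2) / (kB T / e0)))
boltzmann_po <- function(V, z, v_half) {
  1 / (1 + exp(-z * (V - v_half) / thermal_voltage_mV()))
}

#' Steady-state current of each voltage step
#'
#' Averages the current over the last fraction of each step (default the
#' final 20%), where the response has settled.
#'
#' @param steps Output of [generate_macroscopic()] (columns `voltage`,
#'   `time`, `current`).
#' @param last_frac Fraction of the step used for the average.
#' @return A tibble with columns `voltage` (mV) and `current` (pA).
#' @export
measure_steady_state <- function(steps, last_frac = 0.2) {
  stopifnot(all(c("voltage", "time", "current") %in% names(steps)),
            last_frac > 0, last_frac <= 1)
  steps |>
    dplyr::group_by(.data$voltage) |>
    dplyr::filter(.data$time >= (1 - last_frac) * max(.data$time)) |>
    dplyr::summarise(current = mean(.data$current), .groups = "drop")
}
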