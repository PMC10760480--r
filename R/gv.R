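#' Conductance from current-voltage data by Ohm's law
#'
#' \eqn{G = I / (V - V_{rev})}, in nS for I in pA and V in mV. Points at the
#' reversal potential are excluded (conductance undefined there) and flagged
#' with `NA`.
#'
#' @param iv A data frame with columns `voltage` (mV) and `current` (pA).
#' @param v_rev Reversal potential in mV.
#' @return The input tibble with an added `conductance` column (nS).
#' @export
conductance_from_iv <- function(iv, v_rev = 0) {
  stopifnot(all(c("voltage", "current") %in% names(iv)))
  iv <- tibble::as_tibble(iv)
  dv <- iv$voltage - v_rev
  iv$conductance <- ifelse(dv == 0, NA_real_, iv$current / dv)
  attr(iv, "v_rev") <- v_rev
  iv
}

#' Reversal potential from the I-V zero crossing
#'
#' Linear interpolation of the current-voltage relation across its sign
#' change.
#'
#' @param iv A data frame with columns `voltage` (mV) and `current` (pA).
#' @return Estimated reversal potential in mV.
#' @export
estimate_reversal <- function(iv) {
  stopifnot(all(c("voltage", "current") %in% names(iv)))
  o <- order(iv$voltage)
  v <- iv$voltage[o]
  i <- iv$current[o]
  s <- which(i[-length(i)] * i[-1] <= 0 & (i[-length(i)] != 0 | i[-1] != 0))
  if (length(s) == 0) abort("I-V relation does not cross zero")
  k <- s[1]
  v[k] + (0 - i[k]) * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
}

#' Boltzmann fit of a conductance-voltage relation
#'
#' Least-squares fit of
#' \deqn{G(V) = G_{max} / \left(1 + e^{-z (V - V_{1/2}) e_0 / k_B T}\right),}
#' the two-state voltage-activation curve: `z` is the apparent gating
#' valence (e0, positive for activation by depolarization), `V_1/2` the
#' half-activation potential (mV), `G_max` the maximal conductance. Fitted
#' by Levenberg-Marquardt least squares.
#'
#' When the conductance was obtained by Ohm's law (division by `V - V_rev`,
#' see [conductance_from_iv()]), points near the reversal potential carry
#' amplified current noise; the default `weights = "iv"` therefore weights
#' each residual by \eqn{(V - V_{rev})^2}, equivalent to least squares on
#' the underlying currents. Use `weights = "equal"` for plain unweighted
#' fitting (e.g. for already-normalized G-V data of uniform precision).
#'
#' @param gv A data frame with columns `voltage` (mV) and `conductance`
#'   (nS or normalized); `NA` rows are dropped. At least 4 voltages.
#' @param weights `"iv"` (default; requires the `v_rev` attribute set by
#'   [conductance_from_iv()], else falls back to equal weights) or
#'   `"equal"`.
#' @return A `boltzmann_fit`: list with `z`, `v_half`, `g_max`, `delta_g`
#'   (the activation energy `z * v_half`, e0 mV), `vcov`, `fitted`
#'   (tibble), `converged`, and the underlying `nls` object.
#' @seealso [tidy.boltzmann_fit()], [activation_energies()]
#' @export
fit_boltzmann <- function(gv, weights = c("iv", "equal")) {
  stopifnot(all(c("voltage", "conductance") %in% names(gv)))
  weights <- match.arg(weights)
  v_rev <- attr(gv, "v_rev")
  d <- tibble::as_tibble(gv)[, c("voltage", "conductance")]
  d <- d[stats::complete.cases(d), ]
  if (length(unique(d$voltage)) < 4) abort("need at least 4 voltages")
  d$w <- if (weights == "iv" && !is.null(v_rev)) {
    (d$voltage - v_rev)^2
  } else {
    rep(1, nrow(d))
  }
  kt <- thermal_voltage_mV()
  g_max0 <- max(d$conductance)
  v_half0 <- d$voltage[which.min(abs(d$conductance - g_max0 / 2))]
  fit <- minpack.lm::nlsLM(
    conductance ~ g_max / (1 + exp(-z * (voltage - v_half) / kt)),
    data = d,
    weights = d$w,
    start = list(g_max = g_max0, z = 0.8, v_half = v_half0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- coef(fit)
  converged <- fit$convInfo$isConv
  if (!isTRUE(converged)) warn("Boltzmann fit did not converge")
  structure(list(
    z = unname(cf["z"]), v_half = unname(cf["v_half"]),
    g_max = unname(cf["g_max"]),
    delta_g = unname(cf["z"] * cf["v_half"]),
    vcov = vcov(fit),
    fitted = tibble::tibble(voltage = d$voltage,
                            conductance = d$conductance,
                            fitted = predict(fit)),
    converged = isTRUE(converged),
    fit = fit
  ), class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_fit> z = %.4g e0, V1/2 = %.4g mV, Gmax = %.4g, dG = %.4g e0.mV\n",
    x$z, x$v_half, x$g_max, x$delta_g))
  invisible(x)
}

#' Apparent activation energies across permeant-ion conditions
#'
#' For each condition the apparent free energy of activation by voltage is
#' \eqn{\Delta G = z V_{1/2}} (e0 mV; also reported in kJ/mol via the
#' Faraday constant), and \eqn{\Delta\Delta G = \Delta G_{ion} - \Delta
#' G_{ref}} relative to the reference condition (zero for the reference
#' itself; translation-invariant).
#'
#' @param fits A data frame with columns `ion`, `z` (e0) and `v_half` (mV),
#'   or a named list of `boltzmann_fit` objects.
#' @param reference Name of the reference ion (default `"Na"`).
#' @return A tibble with columns `ion`, `z`, `v_half`, `delta_g` (e0 mV),
#'   `delta_g_kj_mol`, `ddg` (e0 mV).
#' @export
activation_energies <- function(fits, reference = "Na") {
  if (!is.data.frame(fits)) {
    fits <- purrr::imap_dfr(fits, function(f, nm) {
      tibble::tibble(ion = nm, z = f$z, v_half = f$v_half)
    })
  }
  stopifnot(all(c("ion", "z", "v_half") %in% names(fits)))
  if (!reference %in% fits$ion) abort("reference ion not present")
  faraday <- 96485.33212 # C/mol
  out <- tibble::as_tibble(fits)
  out$delta_g <- out$z * out$v_half
  out$delta_g_kj_mol <- out$delta_g * 1e-3 * faraday / 1000
  out$ddg <- out$delta_g - out$delta_g[match(reference, out$ion)]
  out
}

#' Fit the exponential voltage dependence of a rate constant
#'
#' Log-linear least-squares fit of \eqn{k(V) = k(0) e^{z V e_0/k_B T}}:
#' regressing \eqn{\log k} on V gives `k0` from the intercept and the
#' apparent charge `z` from the slope times the thermal voltage.
#'
#' @param samples A data frame with columns `voltage` (mV) and `rate`
#'   (s^-1, > 0); at least 2 distinct voltages.
#' @return A [rate_law()] with extra attributes `se_log_k0`, `se_z`,
#'   `r_squared`.
#' @export
fit_rate_voltage <- function(samples) {
  stopifnot(all(c("voltage", "rate") %in% names(samples)),
            all(samples$rate > 0))
  if (length(unique(samples$voltage)) < 2) {
    abort("need at least two distinct voltages")
  }
  kt <- thermal_voltage_mV()
  fit <- lm(log(rate) ~ voltage, data = samples)
  cf <- coef(fit)
  law <- rate_law(exp(unname(cf[1])), unname(cf[2]) * kt)
  # summary.lm warns on numerically perfect (noiseless) fits; harmless here
  sm <- suppressWarnings(summary(fit))
  se <- sqrt(diag(sm$sigma^2 * sm$cov.unscaled))
  attr(law, "se_log_k0") <- unname(se[1])
  attr(law, "se_z") <- unname(se[2]) * kt
  attr(law, "r_squared") <- sm$r.squared
  law
}

#' Normalized open-probability prediction of the star scheme
#'
#' Evaluates the star-scheme open probability over a voltage range using
#' each transition's rate law and normalizes to the maximum over the range —
#' the kinetic-model prediction to compare against a measured G-V curve.
#'
#' @param params A [scheme1_params()] whose entries are [rate_law()]s.
#' @param voltages Voltages in mV.
#' @return A tibble with columns `voltage`, `p_open`, `p_open_norm`.
#' @export
predict_gv_from_scheme <- function(params, voltages = seq(-130, 130, by = 20)) {
  po <- predict_open_probability(params, voltages)
  tibble::tibble(voltage = voltages, p_open = po,
                 p_open_norm = po / max(po))
}
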