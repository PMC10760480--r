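#' Tidy a Boltzmann fit
#'
#' @param x A `boltzmann_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble::tibble(
    term = c("g_max", "z", "v_half"),
    estimate = c(x$g_max, x$z, x$v_half),
    std.error = unname(se[c("g_max", "z", "v_half")])
  )
}

#' @rdname tidy.boltzmann_fit
#' @return `glance()`: one-row tibble with `delta_g` (e0 mV), `sigma`
#'   (residual SD), `n`, `converged`.
#' @export
glance.boltzmann_fit <- function(x, ...) {
  res <- x$fitted$conductance - x$fitted$fitted
  tibble::tibble(delta_g = x$delta_g,
                 sigma = sd(res),
                 n = nrow(x$fitted),
                 converged = x$converged)
}

#' Tidy an exponential-mixture dwell fit
#'
#' @param x An `exp_mixture`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `tau` (s), `weight`.
#' @export
tidy.exp_mixture <- function(x, ...) {
  tibble::tibble(component = seq_len(nrow(x$components)),
                 tau = x$components$tau,
                 weight = x$components$weight)
}

#' @rdname tidy.exp_mixture
#' @export
glance.exp_mixture <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n = x$n,
                 n_components = nrow(x$components),
                 converged = x$converged)
}

#' Tidy an extended-beta rate fit
#'
#' @param x A `scheme1_fit`.
#' @param ... Unused.
#' @return A tibble with columns `rate` and `estimate` (s^-1).
#' @export
tidy.scheme1_fit <- function(x, ...) {
  tibble::tibble(rate = names(x$rates), estimate = unname(x$rates))
}

#' @rdname tidy.scheme1_fit
#' @export
glance.scheme1_fit <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, topology = x$topology,
                 iterations = x$config$iterations,
                 n_sims = x$config$n_sims,
                 n_accepted = x$n_accepted,
                 i_open = x$i_open)
}

#' Tidy a rate law
#'
#' @param x A `rate_law`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (and `std.error` when
#'   the law came from [fit_rate_voltage()]).
#' @export
tidy.rate_law <- function(x, ...) {
  out <- tibble::tibble(term = c("k0", "z"), estimate = c(x$k0, x$z))
  if (!is.null(attr(x, "se_z"))) {
    out$std.error <- c(attr(x, "se_log_k0") * x$k0, attr(x, "se_z"))
  }
  out
}
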