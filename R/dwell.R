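#' Log-binned dwell-time histogram
#'
#' Bins durations on a logarithmic time axis (fixed number of bins per
#' decade), the standard display for multi-exponential dwell-time
#' distributions: each exponential component appears as a peak at its time
#' constant when counts are plotted against log duration.
#'
#' @param durations Dwell durations in seconds (> 0).
#' @param bins_per_decade Number of bins per decade (default 10).
#' @return A `dwell_histogram`: tibble with columns `log10_left`,
#'   `log10_right`, `mid` (s, geometric bin center), `count`; attribute
#'   `bins_per_decade`. Counts sum to `length(durations)`.
#' @export
log_binned_histogram <- function(durations, bins_per_decade = 10) {
  stopifnot(is.numeric(durations), all(durations > 0))
  if (length(durations) == 0) {
    out <- tibble::tibble(log10_left = numeric(), log10_right = numeric(),
                          mid = numeric(), count = integer())
    attr(out, "bins_per_decade") <- bins_per_decade
    class(out) <- c("dwell_histogram", class(out))
    return(out)
  }
  lx <- log10(durations)
  lo <- floor(min(lx) * bins_per_decade) / bins_per_decade
  hi <- ceiling(max(lx) * bins_per_decade) / bins_per_decade
  if (hi <= lo) hi <- lo + 1 / bins_per_decade
  edges <- seq(lo, hi, by = 1 / bins_per_decade)
  idx <- findInterval(lx, edges, rightmost.closed = TRUE)
  cnt <- tabulate(idx, nbins = length(edges) - 1)
  out <- tibble::tibble(
    log10_left = edges[-length(edges)],
    log10_right = edges[-1],
    mid = 10^((edges[-length(edges)] + edges[-1]) / 2),
    count = as.integer(cnt)
  )
  attr(out, "bins_per_decade") <- bins_per_decade
  class(out) <- c("dwell_histogram", class(out))
  out
}

#' Fit a mixture of exponentials to dwell times
#'
#' Maximum-likelihood fit of a left-truncated exponential mixture
#' \deqn{f(d) = \sum_i w_i \tau_i^{-1} e^{-(d - T_d)/\tau_i}, \quad d \ge T_d,}
#' by expectation-maximization. Truncation at the dead time `T_d` accounts
#' for the undetectable short events; each component is a shifted
#' exponential, so for one component the estimator reduces to
#' `mean(d - T_d)`. Components are returned in ascending `tau`.
#'
#' Initialization spreads the components geometrically over the observed
#' duration range (or uses `init_tau` if given).
#'
#' @param durations Dwell durations in seconds, all `>= T_d`.
#' @param n_components Number of exponential components.
#' @param T_d Dead time (s) the data were censored at (default 0).
#' @param init_tau Optional numeric vector of starting time constants.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return An `exp_mixture`: list with `components` (tibble: `tau` s,
#'   `weight`), `loglik`, `converged`, `n`, `T_d`. Non-convergence is
#'   flagged, not an error.
#' @export
fit_dwell_mixture <- function(durations, n_components, T_d = 0,
                              init_tau = NULL, max_iter = 500, tol = 1e-8) {
  d <- durations[is.finite(durations)]
  stopifnot(length(d) >= 10 * n_components, all(d >= T_d), n_components >= 1)
  x <- d - T_d
  x[x <= 0] <- .Machine$double.eps
  n <- length(x)
  if (is.null(init_tau)) {
    qs <- quantile(x, probs = seq(0.1, 0.9, length.out = n_components))
    init_tau <- sort(unique(pmax(qs, .Machine$double.eps)))
    while (length(init_tau) < n_components) {
      init_tau <- c(init_tau, max(init_tau) * 3)
    }
  }
  tau <- sort(init_tau)
  w <- rep(1 / n_components, n_components)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E step: responsibilities under shifted-exponential densities
    logf <- vapply(seq_len(n_components),
                   function(i) log(w[i]) - log(tau[i]) - x / tau[i],
                   numeric(n))
    m <- apply(logf, 1, max)
    p <- exp(logf - m)
    tot <- rowSums(p)
    ll <- sum(m + log(tot))
    r <- p / tot
    # M step
    nk <- colSums(r)
    w <- nk / n
    tau <- colSums(r * x) / nk
    tau[!is.finite(tau) | tau <= 0] <- .Machine$double.eps
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  ord <- order(tau)
  structure(list(
    components = tibble::tibble(tau = tau[ord], weight = w[ord]),
    loglik = ll_old, converged = converged, n = n, T_d = T_d
  ), class = "exp_mixture")
}

#' @export
print.exp_mixture <- function(x, ...) {
  cat(sprintf("<exp_mixture> %d component(s), n = %d, logLik = %.3f%s\n",
              nrow(x$components), x$n, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  tau = %.4g s, weight = %.3f\n",
                x$components$tau[i], x$components$weight[i]))
  }
  invisible(x)
}

#' Critical time separating bursts
#'
#' The gap length `t_c` at which equal numbers of events from the fast
#' (within-burst) and slow (between-burst) closed-time components are
#' misclassified:
#' \deqn{a_f e^{-t_c/\tau_f} = a_s (1 - e^{-t_c/\tau_s}).}
#' The root always lies strictly between \eqn{\tau_f} and \eqn{\tau_s} when
#' the amplitudes are comparable; the solver brackets it inside
#' \eqn{(\tau_f, \tau_s)} and extends the bracket if needed.
#'
#' @param a_f,tau_f Amplitude and time constant (s) of the fast component.
#' @param a_s,tau_s Amplitude and time constant (s) of the slow component;
#'   `tau_f < tau_s` required.
#' @param tol Absolute root tolerance in seconds.
#' @return Critical time in seconds.
#' @examples
#' critical_time(1, 0.001, 1, 0.1) # ~3.4 ms
#' @export
critical_time <- function(a_f, tau_f, a_s, tau_s, tol = 1e-12) {
  stopifnot(a_f > 0, a_s > 0, tau_f > 0, tau_s > 0)
  if (tau_f >= tau_s) abort("tau_f must be smaller than tau_s")
  f <- function(t) a_f * exp(-t / tau_f) - a_s * (1 - exp(-t / tau_s))
  lo <- tau_f
  hi <- tau_s
  # widen the bracket for extreme amplitude ratios
  while (f(lo) < 0 && lo > tau_f * 1e-9) lo <- lo / 2
  while (f(hi) > 0 && hi < tau_s * 1e9) hi <- hi * 2
  uniroot(f, lower = lo, upper = hi, tol = tol)$root
}

#' Pick the component pair defining the critical time
#'
#' Given a fitted closed-time mixture, selects the two adjacent components
#' spanning the largest time-constant ratio (the natural burst/gap boundary)
#' and returns the critical time computed from them.
#'
#' @param mixture An `exp_mixture` fitted to closed dwell times with at
#'   least two components.
#' @return A list with `t_c` (s), `fast` and `slow` (each `list(a, tau)`).
#' @export
critical_time_from_mixture <- function(mixture) {
  stopifnot(inherits(mixture, "exp_mixture"))
  comp <- mixture$components
  if (nrow(comp) < 2) abort("need at least two closed-time components")
  ratios <- comp$tau[-1] / comp$tau[-nrow(comp)]
  i <- which.max(ratios)
  fast <- list(a = comp$weight[i], tau = comp$tau[i])
  slow <- list(a = comp$weight[i + 1], tau = comp$tau[i + 1])
  list(t_c = critical_time(fast$a, fast$tau, slow$a, slow$tau),
       fast = fast, slow = slow)
}
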