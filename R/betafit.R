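#' Star scheme for a given closed-state count
#'
#' Builds the one-open-state gating scheme used in extended-beta fitting:
#' `"1c1o"` uses rates `alpha_o`, `alpha_c`; `"2c1o"` adds `beta_o`,
#' `beta_c`; `"3c1o"` adds `gamma_o`, `gamma_c` (the full star scheme).
#'
#' @param rates Named numeric vector of positive rates in s^-1.
#' @param i_open Open-state amplitude in pA.
#' @return A [gating_scheme()].
#' @export
topology_scheme <- function(rates, i_open = 10) {
  nm <- names(rates)
  need <- topology_rate_names(topology_of(nm))
  stopifnot(all(need %in% nm), all(rates[need] > 0))
  k <- length(need) / 2
  closed <- c("Cs", "Cm", "Cf")[seq_len(k)]
  states <- tibble::tibble(
    label = c("O", closed),
    class = c("open", rep("closed", k)),
    amplitude = c(i_open, rep(0, k))
  )
  pairs <- matrix(need, nrow = 2) # columns: (opening, closing) per closed state
  rt <- tibble::tibble(
    from = as.vector(rbind(closed, "O")),
    to = as.vector(rbind("O", closed)),
    k0 = as.numeric(rates[as.vector(pairs)]),
    z = 0
  )
  gating_scheme(states, rt)
}

topology_rate_names <- function(topology) {
  switch(topology,
    "1c1o" = c("alpha_o", "alpha_c"),
    "2c1o" = c("alpha_o", "alpha_c", "beta_o", "beta_c"),
    "3c1o" = c("alpha_o", "alpha_c", "beta_o", "beta_c", "gamma_o", "gamma_c"),
    abort("unknown topology (use '1c1o', '2c1o' or '3c1o')")
  )
}

topology_of <- function(nm) {
  if (all(c("gamma_o", "gamma_c") %in% nm)) "3c1o"
  else if (all(c("beta_o", "beta_c") %in% nm)) "2c1o"
  else "1c1o"
}

#' Configuration of the zero-order histogram fit
#'
#' Tuning parameters of the stochastic optimizer: `iterations` proposal
#' steps; each proposal's merit is the average of `n_sims` least-squares
#' distances between freshly simulated and experimental histograms
#' (averaging is essential — a single simulated record can score well by
#' chance); each simulated evaluation covers `record_s` seconds of gating.
#' Proposals perturb one randomly chosen rate multiplicatively: a small
#' step (factor uniform on `small_step`, inverted with probability 1/2)
#' refines the current minimum, a large step (factor uniform on
#' `large_step`) escapes local minima; the two are chosen with equal
#' probability.
#'
#' @param iterations Number of optimizer iterations (default 100).
#' @param n_sims Simulations averaged per merit evaluation (default 10).
#' @param record_s Simulated record length per evaluation in seconds.
#' @param small_step,large_step Length-2 numeric ranges of the
#'   multiplicative step factors (> 1).
#' @param seed Integer seed recorded in the fit and used for all
#'   simulation randomness.
#' @return A `beta_fit_config` list.
#' @export
beta_fit_config <- function(iterations = 100, n_sims = 10, record_s = 10,
                            small_step = c(1, 1.1), large_step = c(2, 3),
                            seed = 1) {
  stopifnot(iterations >= 1, n_sims >= 1, record_s > 0,
            length(small_step) == 2, all(small_step >= 1),
            length(large_step) == 2, all(large_step > 1))
  structure(list(iterations = as.integer(iterations),
                 n_sims = as.integer(n_sims), record_s = record_s,
                 small_step = small_step, large_step = large_step,
                 seed = as.integer(seed)),
            class = "beta_fit_config")
}

#' Order star-scheme transition pairs by speed
#'
#' The closed states of a one-open-state star scheme are exchangeable: any
#' permutation of the (opening, closing) pairs describes the same process,
#' so fitted pairs are reported in canonical slow/medium/fast order —
#' sorted by their closing rate, the convention used when classifying
#' transitions by magnitude.
#'
#' @param rates Named vector with the rates of a [topology_scheme()].
#' @return The same vector with pairs relabelled in canonical order.
#' @export
canonicalize_star_rates <- function(rates) {
  nm <- names(rates)
  pairs <- list(c("alpha_o", "alpha_c"), c("beta_o", "beta_c"),
                c("gamma_o", "gamma_c"))
  pairs <- pairs[vapply(pairs, function(p) all(p %in% nm), logical(1))]
  if (length(pairs) < 2) return(rates)
  closing <- vapply(pairs, function(p) rates[[p[2]]], numeric(1))
  ord <- order(closing)
  out <- rates
  for (i in seq_along(pairs)) {
    out[pairs[[i]]] <- rates[pairs[[ord[i]]]]
  }
  out
}

#' Fit sub-bandwidth rate constants by extended beta-distribution analysis
#'
#' Fits the rate constants of a one-open-state gating scheme to an
#' experimental all-points amplitude histogram. Because gating faster than
#' the filter has no analytic amplitude distribution beyond two states, the
#' model histogram is obtained by simulation: each candidate rate set is
#' used to generate filtered, noisy records with the same sampling rate,
#' filter corner and baseline noise as the data, and compared by the
#' least-squares distance of normalized histograms. A zero-order stochastic
#' search (see [beta_fit_config()]) accepts a proposal only when its
#' averaged merit beats the best so far, so the accepted-merit sequence is
#' non-increasing.
#'
#' The open-channel amplitude is not a free parameter: it is fixed to
#' `i_open` (default: the open-peak location of `exp_hist`).
#'
#' @param exp_hist An `amplitude_histogram` of the experimental data,
#'   aligned so the closed peak sits at 0 pA.
#' @param init Named numeric vector of starting rates in s^-1 (names as in
#'   [topology_scheme()]); all positive.
#' @param topology `"1c1o"`, `"2c1o"` or `"3c1o"`.
#' @param i_open Open-channel amplitude in pA.
#' @param f_s,f_c Sampling rate and filter corner frequency (Hz) of the
#'   experimental data.
#' @param noise_sigma Closed-level SD (pA) of the experimental data.
#' @param config A [beta_fit_config()].
#' @return A `scheme1_fit`: list with `rates` (named vector of fitted rates,
#'   s^-1), `chi2` (best averaged merit), `topology`, `i_open`, `trace`
#'   (tibble: iteration, proposal merit, accepted flag, best merit so far),
#'   `config`, `n_accepted`.
#' @export
fit_extended_beta <- function(exp_hist, init, topology = "3c1o",
                              i_open = measured_open_amplitude(exp_hist),
                              f_s = 50000, f_c = 5000, noise_sigma = 1,
                              config = beta_fit_config()) {
  stopifnot(inherits(exp_hist, "amplitude_histogram"),
            inherits(config, "beta_fit_config"))
  need <- topology_rate_names(topology)
  if (!all(need %in% names(init))) {
    abort(paste("init must name rates:", paste(need, collapse = ", ")))
  }
  par <- init[need]
  if (any(!is.finite(par) | par <= 0)) abort("init rates must be positive")

  restore <- local_seed(config$seed)
  on.exit(restore())

  merit <- function(p) {
    mean(vapply(seq_len(config$n_sims), function(i) {
      sim <- simulate_histogram(p, i_open = i_open, f_s = f_s, f_c = f_c,
                                noise_sigma = noise_sigma,
                                record_s = config$record_s,
                                breaks_from = exp_hist)
      histogram_distance(sim, exp_hist)
    }, numeric(1)))
  }

  best_par <- par
  best_R <- merit(par)
  tr <- tibble::tibble(iteration = 0L, merit = best_R, accepted = TRUE,
                       best = best_R)
  n_acc <- 0L
  for (it in seq_len(config$iterations)) {
    j <- sample.int(length(best_par), 1)
    rng <- if (runif(1) < 0.5) config$small_step else config$large_step
    f <- runif(1, rng[1], rng[2])
    if (runif(1) < 0.5) f <- 1 / f
    prop <- best_par
    prop[j] <- prop[j] * f
    if (!is.finite(prop[j]) || prop[j] <= 0) next # reject, never clamp
    R <- merit(prop)
    acc <- R < best_R
    if (acc) {
      best_par <- prop
      best_R <- R
      n_acc <- n_acc + 1L
    }
    tr <- dplyr::bind_rows(tr, tibble::tibble(
      iteration = it, merit = R, accepted = acc, best = best_R))
  }
  structure(list(rates = canonicalize_star_rates(best_par), chi2 = best_R,
                 topology = topology, i_open = i_open, trace = tr,
                 config = config, n_accepted = n_acc),
            class = "scheme1_fit")
}

#' @export
print.scheme1_fit <- function(x, ...) {
  cat(sprintf("<scheme1_fit> topology %s, chi2 = %.5g (%d/%d proposals accepted)\n",
              x$topology, x$chi2, x$n_accepted, x$config$iterations))
  print(round(x$rates, 2))
  invisible(x)
}

#' Heuristic starting rates from an idealized recording
#'
#' Standard-practice initialization for [fit_extended_beta()]: the slow
#' (alpha) pair is estimated from a two-component mixture fit to the
#' resolved closed dwell times (slow component: `alpha_o` from its time
#' constant, `alpha_c` from its event rate per open second); the medium
#' (beta) pair from the fast closed component, whose observed event rate
#' under-counts true medium closures (dead-time clipping) while
#' over-counting them with partially resolved fast-flicker dips — the raw
#' observed rate is therefore used as-is. The fast (gamma) pair is largely
#' invisible to threshold idealization and starts at a generic
#' beyond-bandwidth guess: `gamma_o = 20 f_c`, `gamma_c = 4 f_c` (an
#' order of magnitude past the corner, flicker open fraction ~0.8, typical
#' of flickery channel bursts).
#'
#' @param events A dead-time-censored `event_table` of the recording,
#'   ideally with amplitudes (see [annotate_amplitudes()]).
#' @param f_c Filter corner frequency in Hz.
#' @param topology Target topology (see [topology_scheme()]).
#' @param amp_cut Closed events with mean amplitude at or above this value
#'   (pA) are treated as partial closures and excluded from the medium-band
#'   estimate; `NULL` disables the filter.
#' @return Named numeric vector of starting rates (s^-1).
#' @export
initial_rates_from_trace <- function(events, f_c = 5000, topology = "3c1o",
                                     amp_cut = NULL) {
  closed <- events$duration[events$class == "closed"]
  open_total <- sum(events$duration[events$class == "open"])
  T_d <- dead_time(f_c)
  stopifnot(length(closed) >= 20, open_total > 0)
  mix <- fit_dwell_mixture(closed, n_components = 2, T_d = T_d)
  comp <- mix$components
  n_cl <- length(closed)
  # slow component -> alpha
  alpha_o <- 1 / comp$tau[2]
  alpha_c <- comp$weight[2] * n_cl / open_total
  # medium pair from the band of durations [2.8, 8.4] dead times: below it
  # the apparent durations are contaminated by partially resolved flicker
  # dips, far above it the slow closures dominate. Where event amplitudes
  # are available (annotate_amplitudes()), events that fail to reach the
  # baseline — merged flicker runs — are excluded. tau by doubly truncated
  # exponential MLE on the band; rate corrected by the band's survival and
  # the slow pathway's expected contribution.
  a <- 2.8 * T_d
  b <- 8.4 * T_d
  is_cl <- events$class == "closed"
  full <- if ("amplitude" %in% names(events) && !is.null(amp_cut)) {
    !is.na(events$amplitude) & events$amplitude < amp_cut
  } else rep(TRUE, nrow(events))
  band <- events$duration[is_cl & full &
                            events$duration >= a & events$duration < b]
  if (length(band) >= 20) {
    tau_b <- band_tau_mle(band, a, b, T_d)
    surv <- exp(-a / tau_b) - exp(-b / tau_b)
    tau_a <- comp$tau[2]
    alpha_in_band <- alpha_c * (exp(-a / tau_a) - exp(-b / tau_a))
    beta_o <- 1 / tau_b
    beta_c <- max((length(band) / open_total - alpha_in_band) / surv,
                  0.05 * length(band) / open_total / surv)
  } else {
    # too few resolved medium closures: fall back on the fast mixture
    # component (biased short by flicker-dip contamination)
    beta_o <- 1 / comp$tau[1]
    beta_c <- comp$weight[1] * n_cl / open_total
  }
  out <- c(alpha_o = alpha_o, alpha_c = alpha_c,
           beta_o = beta_o, beta_c = beta_c,
           gamma_o = 20 * f_c, gamma_c = 4 * f_c)
  out[topology_rate_names(topology)]
}

# doubly truncated exponential MLE on a duration band [a, b); optimized on
# the log scale (tau spans orders of magnitude below optimize()'s default
# absolute tolerance)
band_tau_mle <- function(band, a, b, T_d) {
  nll <- function(ltau) {
    tau <- exp(ltau)
    length(band) * log(tau * (exp(-a / tau) - exp(-b / tau))) +
      sum(band) / tau
  }
  exp(optimize(nll, log(c(T_d / 2, 20 * T_d)), tol = 1e-6)$minimum)
}

#' Refine starting rates by dwell-rate calibration and a coarse merit scan
#'
#' The amplitude-histogram merit constrains the *sum* of closed/open
#' occupancy ratios tightly (it fixes the mean current) but splits it
#' between the medium and fast pathways only weakly at realistic record
#' lengths: raising `beta_c` while lowering the fast flicker leaves the
#' histogram nearly unchanged. The idealized event sequence carries the
#' missing information, and this refinement uses it in three steps:
#'
#' 1. **Calibrate the slow and medium pairs** by indirect inference on two
#'    duration bands of the censored closed events: full-amplitude
#'    closures in `[2.8, 8.4] * T_d` (dominated by genuine medium
#'    closures — partially resolved fast-flicker dips cluster just above
#'    the dead time or retain elevated amplitudes) and all closures in
#'    `[8.4, 50] * T_d` (dominated by the slow pathway). For each band,
#'    two statistics — the event rate per open second and the apparent
#'    truncated-exponential time constant — are measured identically on
#'    the experimental events and on an idealized simulation at the
#'    current rates, and the corresponding opening/closing rates are
#'    updated by damped fixed-point steps toward agreement. Matching
#'    *simulated* statistics absorbs the detection artifacts (duration
#'    stretching by merged flickers, blob contamination, jitter) that
#'    closed-form missed-events corrections cannot capture; at the fixed
#'    point the model reproduces the observed bands exactly.
#' 2. **Pin the fast-pair ratio** from the measured mean current: since
#'    the histogram mean equals \eqn{P_O i_{open}} exactly,
#'    \eqn{\gamma_c/\gamma_o} is set so the star-scheme open probability
#'    reproduces it given the other four rates.
#' 3. **Scan the fast-pair magnitude** (both rates scaled together over
#'    factors 1/2, 1, 2, 4, which preserves the ratio and hence the mean)
#'    with a short-record histogram merit, keeping the best.
#'
#' The subsequent [fit_extended_beta()] run then refines rather than
#' explores.
#'
#' @param init Named starting rates (from [initial_rates_from_trace()]).
#' @param exp_hist Experimental `amplitude_histogram`.
#' @param events Dead-time-censored `event_table` of the experimental
#'   trace (enables the `beta_c` calibration; omit to skip it).
#' @param i_open,f_s,f_c,noise_sigma Recording condition (as in
#'   [fit_extended_beta()]).
#' @param record_s,n_sims Simulation size per calibration/scan evaluation.
#' @param cycles Number of calibrate/pin/scan passes (the first pass
#'   calibrates against a still-generic fast pair; a second pass
#'   re-calibrates with the refined one).
#' @param long_cut Duration cut of the calibration statistic, in dead
#'   times.
#' @param seed Integer seed for the refinement's simulations.
#' @return The refined named rate vector.
#' @export
refine_initial_rates <- function(init, exp_hist, events = NULL, i_open = 10,
                                 f_s = 50000, f_c = 5000, noise_sigma = 1,
                                 record_s = 10, n_sims = 3, cycles = 3,
                                 long_cut = 2.8, seed = 1) {
  if (!all(c("gamma_o", "gamma_c") %in% names(init))) return(init)
  restore <- local_seed(seed)
  on.exit(restore())
  T_d <- dead_time(f_c)
  cut <- long_cut * T_d
  top_edge <- 3 * cut
  r <- init

  amp_cut <- 0.3 * i_open
  band_stats <- function(ev) {
    full <- if ("amplitude" %in% names(ev)) {
      !is.na(ev$amplitude) & ev$amplitude < amp_cut
    } else rep(TRUE, nrow(ev))
    closed <- ev$class == "closed"
    open_t <- sum(ev$duration[ev$class == "open"])
    med <- closed & full & ev$duration >= cut & ev$duration < top_edge
    # slow pair via the classical two-component mixture estimator applied
    # identically to observed and simulated events: matching the *apparent*
    # estimate cancels its contamination bias
    mix <- tryCatch(
      fit_dwell_mixture(ev$duration[closed], 2, T_d = T_d),
      error = function(e) NULL)
    c(rate = sum(med) / open_t,
      tau = if (sum(med) >= 10) {
        band_tau_mle(ev$duration[med], cut, top_edge, T_d)
      } else NA_real_,
      alpha_o_hat = if (!is.null(mix)) 1 / mix$components$tau[2] else NA_real_,
      alpha_c_hat = if (!is.null(mix)) {
        mix$components$weight[2] * sum(closed) / open_t
      } else NA_real_)
  }
  sim_band_stats <- function(rates) {
    sch <- topology_scheme(rates, i_open)
    p <- simulate_state_path(sch, 2 * record_s)
    tr <- render_trace(p, f_s = f_s, f_c = f_c, noise_sigma = noise_sigma)
    ev <- apply_dead_time(idealize_half_amplitude(tr, i_open = i_open), T_d)
    band_stats(annotate_amplitudes(ev, tr))
  }

  merit <- function(rr, ns = n_sims) {
    mean(vapply(seq_len(ns), function(i) {
      histogram_distance(
        simulate_histogram(rr, i_open = i_open, f_s = f_s, f_c = f_c,
                           noise_sigma = noise_sigma, record_s = record_s,
                           breaks_from = exp_hist), exp_hist)
    }, numeric(1)))
  }

  po_obs <- sum(exp_hist$mid * exp_hist$density) / i_open
  obs <- if (!is.null(events)) band_stats(events) else NULL
  clamp <- function(f) max(1 / 1.5, min(1.5, f))

  for (cyc in seq_len(cycles)) {
    if (!is.null(obs) && obs[["rate"]] > 0) {
      sim <- sim_band_stats(r)
      # damped fixed-point updates, capped at x/1.5 per cycle: the model's
      # apparent band time constant falls as beta_o rises, and the band
      # rate grows with beta_c
      if (is.finite(sim[["tau"]]) && is.finite(obs[["tau"]])) {
        r[["beta_o"]] <- r[["beta_o"]] * clamp(sim[["tau"]] / obs[["tau"]])
      }
      if (is.finite(sim[["rate"]]) && sim[["rate"]] > 0) {
        r[["beta_c"]] <- r[["beta_c"]] * clamp(obs[["rate"]] / sim[["rate"]])
      }
      # slow pair: match the apparent mixture estimates
      if (is.finite(sim[["alpha_o_hat"]]) && is.finite(obs[["alpha_o_hat"]])) {
        r[["alpha_o"]] <- r[["alpha_o"]] *
          clamp(obs[["alpha_o_hat"]] / sim[["alpha_o_hat"]])
      }
      if (is.finite(sim[["alpha_c_hat"]]) && sim[["alpha_c_hat"]] > 0) {
        r[["alpha_c"]] <- r[["alpha_c"]] *
          clamp(obs[["alpha_c_hat"]] / sim[["alpha_c_hat"]])
      }
    }
    # fast-pair ratio from the measured mean current (P_O * i_open)
    if (po_obs > 0 && po_obs < 1) {
      resid <- 1 / po_obs - 1 -
        r[["alpha_c"]] / r[["alpha_o"]] - r[["beta_c"]] / r[["beta_o"]]
      if (resid > 0) r[["gamma_c"]] <- r[["gamma_o"]] * resid
    }
    # fast-pair magnitude scan (ratio-preserving, so the mean is kept);
    # the final cycle rescans a finer grid at doubled precision
    last <- cyc == cycles
    grid <- if (last) c(1 / 1.4, 1 / 1.2, 1, 1.2, 1.4) else c(0.5, 1 / 1.4, 1, 1.4, 2, 4)
    ns <- if (last) 2 * n_sims else n_sims
    best <- r
    best_m <- Inf
    for (gf in grid) {
      rr <- r
      rr[["gamma_o"]] <- r[["gamma_o"]] * gf
      rr[["gamma_c"]] <- r[["gamma_c"]] * gf
      m <- merit(rr, ns)
      if (m < best_m) {
        best_m <- m
        best <- rr
      }
    }
    r <- best
  }
  r
}
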