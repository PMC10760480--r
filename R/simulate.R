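#' Draw exponential dwell times for a state
#'
#' A sojourn in Markov state i ends after \eqn{d = -\ln(R)/\sum_j k_{ij}}
#' seconds, with R uniform on (0, 1) and the sum running over all exit rates.
#'
#' @param scheme A [gating_scheme()].
#' @param state State label.
#' @param V Membrane potential in mV.
#' @param n Number of draws.
#' @return Numeric vector of dwell durations in seconds.
#' @export
sample_dwell <- function(scheme, state, V = 0, n = 1) {
  stopifnot(inherits(scheme, "gating_scheme"))
  idx <- scheme$rates$from == state
  if (!any(idx)) abort(paste0("state '", state, "' has no exits (absorbing)"))
  total <- sum(purrr::map_dbl(scheme$rates$law[idx], rate_at_voltage, V = V))
  -log(runif(n)) / total
}

# cumulative branching-probability matrix for the C++ simulator
scheme_cumprob <- function(scheme, V) {
  lab <- scheme$states$label
  n <- length(lab)
  P <- matrix(0, n, n, dimnames = list(lab, lab))
  for (s in lab) {
    idx <- scheme$rates$from == s
    if (!any(idx)) abort(paste0("state '", s, "' has no exits (absorbing)"))
    k <- purrr::map_dbl(scheme$rates$law[idx], rate_at_voltage, V = V)
    P[s, scheme$rates$to[idx]] <- k / sum(k)
  }
  t(apply(P, 1, cumsum))
}

#' Monte Carlo simulation of a gating state path
#'
#' Simulates the continuous-time Markov chain defined by `scheme` at voltage
#' `V` for `duration` seconds: dwell times are exponential with the state's
#' total exit rate, successors are drawn from the embedded-chain branching
#' probabilities. The last dwell is truncated at `duration`. The initial state
#' is drawn from the stationary distribution unless `start_state` is given.
#'
#' @param scheme A [gating_scheme()].
#' @param duration Simulated time in seconds (>= 0).
#' @param V Membrane potential in mV.
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @param start_state Optional state label to start in.
#' @return A `dwell_sequence`: tibble with columns `state`, `class`,
#'   `amplitude` (pA), `start` (s), `duration` (s).
#' @examples
#' sch <- as_gating_scheme(scheme1_params(1500, 27, 22500, 600, 127500, 30000))
#' path <- simulate_state_path(sch, duration = 0.01, seed = 1)
#' open_fraction(path)
#' @export
simulate_state_path <- function(scheme, duration, V = 0, seed = NULL,
                                start_state = NULL) {
  stopifnot(inherits(scheme, "gating_scheme"), duration >= 0)
  restore <- local_seed(seed)
  on.exit(restore())
  lab <- scheme$states$label
  if (duration == 0) {
    return(new_dwell_sequence(tibble::tibble(
      state = character(), class = character(), amplitude = numeric(),
      start = numeric(), duration = numeric())))
  }
  Q <- scheme_rate_matrix(scheme, V)
  exit <- -diag(Q)
  cum <- scheme_cumprob(scheme, V)
  if (is.null(start_state)) {
    occ <- steady_state_occupancy(scheme, V)$occupancy
    start_state <- lab[findInterval(runif(1), cumsum(occ)) + 1]
  }
  s0 <- match(start_state, lab)
  if (is.na(s0)) abort("unknown start state")
  res <- sim_path_cpp(exit, cum, s0 - 1L, duration)
  st <- res$state + 1L
  d <- res$duration
  out <- tibble::tibble(
    state = lab[st],
    class = scheme$states$class[st],
    amplitude = scheme$states$amplitude[st],
    start = cumsum(c(0, d[-length(d)])),
    duration = d
  )
  new_dwell_sequence(out)
}

new_dwell_sequence <- function(x) {
  class(x) <- c("dwell_sequence", class(x))
  x
}

#' Simulate a state path whose dwells all exceed a minimum duration
#'
#' Variant of [simulate_state_path()] in which every dwell is drawn from the
#' state's exit-rate exponential left-truncated at `t_min` (equivalently
#' `t_min` plus an exponential, by memorylessness), while successors follow
#' the embedded-chain branching probabilities. Used to build ground-truth
#' recordings in which every event is long enough to be resolved by a given
#' filter (`t_min` of order `10 / f_c`). For schemes whose open and closed
#' mean dwells are comparable the open-time fraction stays within a fraction
#' of a percent of the untruncated steady state.
#'
#' @inheritParams simulate_state_path
#' @param t_min Minimum dwell duration in seconds.
#' @return A `dwell_sequence` (see [simulate_state_path()]).
#' @export
simulate_resolvable_path <- function(scheme, duration, t_min, V = 0,
                                     seed = NULL, start_state = NULL) {
  stopifnot(inherits(scheme, "gating_scheme"), duration >= 0, t_min >= 0)
  restore <- local_seed(seed)
  on.exit(restore())
  Q <- scheme_rate_matrix(scheme, V)
  lab <- scheme$states$label
  st <- if (is.null(start_state)) {
    occ <- steady_state_occupancy(scheme, V)$occupancy
    lab[findInterval(runif(1), cumsum(occ)) + 1]
  } else start_state
  branching <- lapply(lab, function(s) transition_probabilities(scheme, s, V))
  names(branching) <- lab
  t <- 0
  out_s <- character(0)
  out_d <- numeric(0)
  while (t < duration) {
    d <- t_min + rexp(1, -Q[st, st])
    if (t + d > duration) d <- duration - t
    out_s <- c(out_s, st)
    out_d <- c(out_d, d)
    t <- t + d
    tp <- branching[[st]]
    st <- tp$to[findInterval(runif(1), cumsum(tp$p)) + 1]
  }
  idx <- match(out_s, lab)
  new_dwell_sequence(tibble::tibble(
    state = out_s,
    class = scheme$states$class[idx],
    amplitude = scheme$states$amplitude[idx],
    start = cumsum(c(0, out_d[-length(out_d)])),
    duration = out_d
  ))
}

#' Fraction of time spent open in a dwell sequence or event table
#'
#' @param path A `dwell_sequence` or `event_table` (anything with `class` and
#'   `duration` columns).
#' @return Scalar open-time fraction.
#' @export
open_fraction <- function(path) {
  stopifnot(all(c("class", "duration") %in% names(path)))
  sum(path$duration[path$class == "open"]) / sum(path$duration)
}

#' Impulse response of the Gaussian filter
#'
#' Analog low-pass filtering of patch-clamp recordings is modelled as
#' convolution with a Gaussian impulse response
#' \eqn{H(t) = (2\pi\sigma_g^2)^{-1/2} \exp(-t^2/2\sigma_g^2)}, with
#' \eqn{\sigma_g = \sqrt{\ln 2}/(2\pi f_c)} set by the -3 dB corner frequency
#' `f_c`. `gaussian_filter_sigma()` returns \eqn{\sigma_g} in seconds;
#' `gaussian_filter_kernel()` the discrete unit-sum kernel sampled at `f_s`
#' and truncated at 5 standard deviations.
#'
#' @param f_c Filter corner frequency in Hz (-3 dB).
#' @param f_s Sampling rate in Hz.
#' @return `gaussian_filter_sigma()`: seconds. `gaussian_filter_kernel()`: an
#'   odd-length numeric vector summing to 1.
#' @examples
#' gaussian_filter_sigma(5000) # ~26.5 microseconds
#' @export
gaussian_filter_sigma <- function(f_c) {
  stopifnot(f_c > 0)
  sqrt(log(2)) / (2 * pi * f_c)
}

#' @rdname gaussian_filter_sigma
#' @export
gaussian_filter_kernel <- function(f_c, f_s) {
  sg <- gaussian_filter_sigma(f_c) * f_s # sigma in samples
  L <- max(1L, ceiling(5 * sg))
  k <- seq(-L, L)
  h <- exp(-k^2 / (2 * sg^2))
  h / sum(h)
}

# circular convolution with a short odd-length kernel; exact DC gain 1
convolve_circular <- function(x, h) {
  n <- length(x)
  L <- (length(h) - 1L) / 2L
  if (n <= 2L * L) {
    # short trace: direct wrapped sum
    out <- numeric(n)
    for (j in seq_along(h)) {
      out <- out + h[j] * x[((seq_len(n) - 1L + j - 1L - L) %% n) + 1L]
    }
    return(out)
  }
  xp <- c(tail(x, L), x, head(x, L))
  as.numeric(stats::filter(xp, h, method = "convolution", sides = 2))[(L + 1L):(L + n)]
}

#' Render a dwell sequence as a sampled, filtered, noisy current trace
#'
#' Builds the infinite-bandwidth current (state amplitude: 0 pA closed,
#' `i_open` pA open) point-sampled at `f_s`, adds white Gaussian baseline
#' noise, and convolves with the discrete Gaussian filter kernel for corner
#' frequency `f_c`. `noise_sigma` specifies the *post-filter* closed-level
#' standard deviation: the pre-filter white noise SD is scaled up by the
#' filter's noise-bandwidth gain so the rendered baseline SD matches.
#' With `f_c = Inf` no filtering is applied.
#'
#' @param path A `dwell_sequence` (from [simulate_state_path()] or built
#'   directly).
#' @param i_open Open-channel amplitude in pA; if `NULL`, the `amplitude`
#'   column of `path` is used as-is.
#' @param f_s Sampling rate in Hz. Must exceed `2 * f_c`.
#' @param f_c Filter corner frequency in Hz (default 5 kHz).
#' @param noise_sigma Post-filter closed-level SD in pA (>= 0).
#' @param seed Optional integer seed for the noise.
#' @param V Holding potential in mV, stored as trace metadata.
#' @return A `sampled_trace`: tibble with columns `time` (s) and `current`
#'   (pA), with attributes `f_s`, `f_c`, `noise_sigma`, `V`.
#' @export
render_trace <- function(path, i_open = NULL, f_s = 50000, f_c = 5000,
                         noise_sigma = 1, seed = NULL, V = NA_real_) {
  stopifnot(all(c("class", "duration") %in% names(path)),
            nrow(path) > 0, all(path$duration > 0), noise_sigma >= 0)
  if (is.finite(f_c) && f_s <= 2 * f_c) {
    abort("sampling rate must exceed twice the filter corner frequency")
  }
  restore <- local_seed(seed)
  on.exit(restore())
  amp <- if (is.null(i_open)) {
    stopifnot("amplitude" %in% names(path))
    path$amplitude
  } else {
    ifelse(path$class == "open", i_open, 0)
  }
  total <- sum(path$duration)
  n <- floor(total * f_s)
  if (n < 1) abort("record shorter than one sample")
  x <- point_sample_cpp(cumsum(path$duration), amp, as.integer(n), f_s)
  if (is.finite(f_c)) {
    h <- gaussian_filter_kernel(f_c, f_s)
    if (noise_sigma > 0) {
      x <- x + rnorm(n, sd = noise_sigma / sqrt(sum(h^2)))
    }
    x <- convolve_circular(x, h)
  } else if (noise_sigma > 0) {
    x <- x + rnorm(n, sd = noise_sigma)
  }
  new_sampled_trace(x, f_s = f_s, f_c = f_c, noise_sigma = noise_sigma, V = V)
}

new_sampled_trace <- function(current, f_s, f_c, noise_sigma = NA_real_,
                              V = NA_real_) {
  out <- tibble::tibble(
    time = (seq_along(current) - 0.5) / f_s,
    current = as.numeric(current)
  )
  attr(out, "f_s") <- f_s
  attr(out, "f_c") <- f_c
  attr(out, "noise_sigma") <- noise_sigma
  attr(out, "V") <- V
  class(out) <- c("sampled_trace", class(out))
  out
}

#' Trace metadata accessors
#'
#' @param trace A `sampled_trace`.
#' @return Scalar metadata value.
#' @export
trace_f_s <- function(trace) attr(trace, "f_s")

#' @rdname trace_f_s
#' @export
trace_f_c <- function(trace) attr(trace, "f_c")

#' Simulate a single-channel recording end to end
#'
#' Convenience composition: [simulate_state_path()] then [render_trace()],
#' returning both the ground-truth path and the rendered trace. The default
#' condition mirrors typical high-resolution recordings: 50 kHz sampling,
#' 5 kHz Gaussian filtering.
#'
#' @inheritParams simulate_state_path
#' @inheritParams render_trace
#' @return A list with elements `path` (`dwell_sequence`) and `trace`
#'   (`sampled_trace`).
#' @export
simulate_recording <- function(scheme, duration, V = 0, f_s = 50000,
                               f_c = 5000, noise_sigma = 1, seed = NULL) {
  restore <- local_seed(seed)
  on.exit(restore())
  path <- simulate_state_path(scheme, duration, V = V)
  trace <- render_trace(path, i_open = NULL, f_s = f_s, f_c = f_c,
                        noise_sigma = noise_sigma, V = V)
  list(path = path, trace = trace)
}

# set.seed scoped to the calling computation: returns a restore function
local_seed <- function(seed) {
  if (is.null(seed)) return(function() invisible())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
    invisible()
  }
}
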