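#' All-points amplitude histogram
#'
#' Accumulates every current sample of the supplied segments into uniform
#' amplitude bins. The shape of this histogram encodes gating faster than
#' the filter: fully resolved levels give Gaussian peaks, sub-bandwidth
#' flicker gives asymmetric tails between the levels. With `align = TRUE`
#' the closed-state peak (the lowest-amplitude prominent mode, refined by
#' parabolic interpolation) is shifted to 0 pA, the conventional display
#' and the anchor used when fitting simulated histograms.
#'
#' @param segments A numeric vector of currents (pA), a `sampled_trace`, or
#'   a list of either.
#' @param bin_width Bin width in pA.
#' @param align Logical: shift the closed-state peak to 0 pA? Use `FALSE`
#'   for traces synthesized at a known zero baseline — at high open
#'   probability the closed level can be a shoulder of the flicker tail
#'   rather than a distinct mode, in which case re-anchoring is
#'   unreliable (a warning is raised and no shift applied).
#' @param baseline_guess Rough closed-level current (pA) used to pick the
#'   closed peak among the histogram's modes.
#' @param search_halfwidth Maximum distance (pA) from `baseline_guess` at
#'   which a mode is accepted as the closed peak.
#' @return An `amplitude_histogram`: tibble with columns `mid` (bin center,
#'   pA), `count`, `density` (probability mass per bin, summing to 1), with
#'   attributes `bin_width`, `n` (samples accumulated), `align_shift`.
#' @export
all_points_histogram <- function(segments, bin_width = 0.2, align = TRUE,
                                 baseline_guess = 0,
                                 search_halfwidth = Inf) {
  x <- gather_currents(segments)
  if (length(x) == 0) abort("no samples in segments")
  stopifnot(bin_width > 0)
  lo <- floor(min(x) / bin_width) * bin_width - bin_width / 2
  nb <- ceiling((max(x) - lo) / bin_width) + 1L
  cnt <- bin_counts_cpp(x, lo, bin_width, as.integer(nb))
  mids <- lo + (seq_len(nb) - 0.5) * bin_width
  shift <- 0
  if (align) {
    cand <- peak_locations(mids, cnt)
    cand <- cand[abs(cand - baseline_guess) <= search_halfwidth]
    if (length(cand) == 0) {
      warn("no closed-state mode near the baseline guess; histogram left unshifted")
    } else {
      shift <- cand[which.min(abs(cand - baseline_guess))]
      mids <- mids - shift
    }
  }
  new_amplitude_histogram(mids, cnt, bin_width, align_shift = shift)
}

gather_currents <- function(segments) {
  if (is.data.frame(segments)) return(segments$current)
  if (is.list(segments)) {
    return(unlist(purrr::map(segments, gather_currents), use.names = FALSE))
  }
  as.numeric(segments)
}

new_amplitude_histogram <- function(mids, counts, bin_width, align_shift = 0) {
  n <- sum(counts)
  out <- tibble::tibble(mid = mids, count = as.numeric(counts),
                        density = if (n > 0) counts / n else counts * 0)
  attr(out, "bin_width") <- bin_width
  attr(out, "n") <- n
  attr(out, "align_shift") <- align_shift
  class(out) <- c("amplitude_histogram", class(out))
  out
}

# all prominent peak locations, ascending in amplitude; a peak must exceed
# its neighbours within +/-2 bins of the smoothed counts so Poisson wiggles
# on histogram tails do not qualify
peak_locations <- function(mids, cnt) {
  k <- length(cnt)
  if (k < 5) return(mids[which.max(cnt)])
  sm <- as.numeric(stats::filter(c(cnt[c(1, 1)], cnt, cnt[c(k, k)]),
                                 rep(1 / 5, 5), sides = 2))[3:(k + 2)]
  lag2 <- function(x, s) { # shift with edge padding
    if (s > 0) c(rep(-Inf, s), x[seq_len(k - s)])
    else c(x[(1 - s):k], rep(-Inf, -s))
  }
  is_peak <- sm >= lag2(sm, 1) & sm > lag2(sm, -1) &
    sm >= lag2(sm, 2) & sm > lag2(sm, -2) &
    sm >= 0.003 * max(sm)
  idx <- which(is_peak)
  if (length(idx) == 0) idx <- which.max(sm)
  vapply(idx, function(i) refine_peak(mids, sm, i), numeric(1))
}

refine_peak <- function(mids, cnt, i) {
  if (i <= 1 || i >= length(cnt)) return(mids[i])
  y <- log(pmax(cnt[(i - 1):(i + 1)], 0.5))
  den <- y[1] - 2 * y[2] + y[3]
  if (den >= 0) return(mids[i])
  mids[i] + 0.5 * (y[1] - y[3]) / den * (mids[2] - mids[1])
}

#' Open-peak amplitude of a histogram
#'
#' The measured open-channel level, used to fix `i_open` during
#' extended-beta fitting. By default this is the highest-amplitude
#' prominent mode; when `noise_sigma` is supplied the level is instead
#' estimated from the right flank of the open peak (the half-maximum
#' crossing minus \eqn{\sigma\sqrt{2\ln 2}}), which is insensitive to the
#' flicker tail that skews the peak's apex towards lower amplitudes.
#'
#' @param hist An `amplitude_histogram`.
#' @param noise_sigma Optional closed-level SD in pA enabling the
#'   flank-based estimate.
#' @return Amplitude in pA.
#' @export
measured_open_amplitude <- function(hist, noise_sigma = NULL) {
  stopifnot(inherits(hist, "amplitude_histogram"))
  p <- peak_locations(hist$mid, hist$count)
  mode <- p[length(p)]
  if (is.null(noise_sigma)) return(mode)
  # Gaussian regression on the right flank: with the baseline-noise SD
  # fixed, log density + x^2/(2 sigma^2) is linear in x with slope
  # mu/sigma^2 for a Gaussian flank centred at mu
  keep <- hist$mid >= mode + 0.3 * noise_sigma &
    hist$mid <= mode + 2.5 * noise_sigma & hist$count > 20
  if (sum(keep) < 4) return(mode)
  y <- log(hist$density[keep]) + hist$mid[keep]^2 / (2 * noise_sigma^2)
  x <- hist$mid[keep]
  unname(coef(lm(y ~ x))[2]) * noise_sigma^2
}

#' Extract burst segments (plus baseline padding) from a trace
#'
#' Automates burst selection for amplitude-histogram analysis: bursts are
#' located with [segment_bursts()] at critical time `t_c` and each is
#' extracted with `pad` seconds of flanking baseline, so the closed-level
#' peak is represented and the zero-current level can be anchored.
#' Overlapping padded windows are merged.
#'
#' @param events An `event_table` for `trace`.
#' @param trace The corresponding `sampled_trace`.
#' @param t_c Critical time in seconds.
#' @param pad Baseline padding on each side, in seconds.
#' @return A list of numeric current vectors (possibly empty).
#' @export
select_bursts_for_histogram <- function(events, trace, t_c, pad = 0) {
  bursts <- segment_bursts(events, t_c)
  if (nrow(bursts) == 0) return(list())
  f_s <- attr(trace, "f_s")
  t0 <- trace$time[1]
  lo <- pmax(bursts$start - pad, t0)
  hi <- pmin(bursts$start + bursts$length + pad, trace$time[nrow(trace)])
  # merge overlapping windows
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  keep_lo <- lo[1]; keep_hi <- hi[1]
  out_lo <- c(); out_hi <- c()
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= keep_hi) {
      keep_hi <- max(keep_hi, hi[i])
    } else {
      out_lo <- c(out_lo, keep_lo); out_hi <- c(out_hi, keep_hi)
      keep_lo <- lo[i]; keep_hi <- hi[i]
    }
  }
  out_lo <- c(out_lo, keep_lo); out_hi <- c(out_hi, keep_hi)
  i_lo <- pmax(1L, ceiling((out_lo - t0) * f_s) + 1L)
  i_hi <- pmin(nrow(trace), floor((out_hi - t0) * f_s) + 1L)
  purrr::map2(i_lo, i_hi, function(a, b) trace$current[a:b])
}

#' Simulate an amplitude histogram from a kinetic scheme
#'
#' Composes the synthetic-data pipeline — Monte Carlo gating, point
#' sampling, baseline noise, Gaussian filtering — and bins the resulting
#' samples, optionally on the binning of an experimental histogram (pass
#' `breaks_from`). This is the forward model of extended beta-distribution
#' fitting: the theoretical amplitude distribution of a filtered
#' finite-state gating process, obtained by simulation.
#'
#' @param params A [scheme1_params()], [gating_scheme()], or named rate
#'   vector accepted by [topology_scheme()].
#' @param i_open Open-channel amplitude in pA.
#' @param f_s,f_c Sampling rate and filter corner (Hz).
#' @param noise_sigma Post-filter closed-level SD (pA).
#' @param record_s Simulated record length in seconds.
#' @param seed Optional integer seed.
#' @param breaks_from Optional `amplitude_histogram` whose binning to reuse.
#' @param bin_width Bin width (pA) when `breaks_from` is not given.
#' @return An `amplitude_histogram` (normalized density). Samples falling
#'   outside an imposed binning are dropped.
#' @export
simulate_histogram <- function(params, i_open = 10, f_s = 50000, f_c = 5000,
                               noise_sigma = 1, record_s = 10, seed = NULL,
                               breaks_from = NULL,
                               bin_width = if (noise_sigma > 0)
                                 noise_sigma / 5 else abs(i_open) / 50) {
  restore <- local_seed(seed)
  on.exit(restore())
  scheme <- if (inherits(params, "gating_scheme")) params
    else if (inherits(params, "scheme1_params")) as_gating_scheme(params, i_open)
    else topology_scheme(params, i_open)
  path <- simulate_state_path(scheme, record_s)
  trace <- render_trace(path, i_open = NULL, f_s = f_s, f_c = f_c,
                        noise_sigma = noise_sigma)
  if (is.null(breaks_from)) {
    all_points_histogram(trace$current, bin_width = bin_width, align = FALSE)
  } else {
    bw <- attr(breaks_from, "bin_width")
    lo <- breaks_from$mid[1] - bw / 2
    cnt <- bin_counts_cpp(trace$current, lo, bw, as.integer(nrow(breaks_from)))
    new_amplitude_histogram(breaks_from$mid, cnt, bw)
  }
}

#' Least-squares distance between two amplitude histograms
#'
#' Sum of squared differences of the normalized densities, the chi-square
#' merit used when fitting simulated to experimental histograms. Symmetric,
#' nonnegative, zero iff identical. The histograms must share their binning
#' (use [rebin_histogram()] first if they do not).
#'
#' @param h1,h2 `amplitude_histogram` objects on identical bins.
#' @return Scalar chi-square.
#' @export
histogram_distance <- function(h1, h2) {
  stopifnot(inherits(h1, "amplitude_histogram"),
            inherits(h2, "amplitude_histogram"))
  if (nrow(h1) != nrow(h2) ||
      max(abs(h1$mid - h2$mid)) > 1e-9 * attr(h1, "bin_width")) {
    abort("histograms are on different bins; rebin_histogram() first")
  }
  sum((h1$density - h2$density)^2)
}

#' Rebin an amplitude histogram onto new bins
#'
#' Redistributes counts by proportional bin overlap onto the binning of a
#' template histogram.
#'
#' @param h An `amplitude_histogram`.
#' @param template An `amplitude_histogram` supplying the target bins.
#' @return An `amplitude_histogram` on the template bins.
#' @export
rebin_histogram <- function(h, template) {
  bw_old <- attr(h, "bin_width")
  bw_new <- attr(template, "bin_width")
  old_lo <- h$mid - bw_old / 2
  old_hi <- h$mid + bw_old / 2
  new_lo <- template$mid - bw_new / 2
  new_hi <- template$mid + bw_new / 2
  cnt <- vapply(seq_along(new_lo), function(j) {
    ov <- pmin(old_hi, new_hi[j]) - pmax(old_lo, new_lo[j])
    sum(h$count * pmax(ov, 0) / bw_old)
  }, numeric(1))
  new_amplitude_histogram(template$mid, cnt, bw_new)
}
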