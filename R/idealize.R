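#' Filter dead time
#'
#' The shortest event reliably detected after Gaussian filtering,
#' \eqn{T_d = 0.179 / f_c}. At \eqn{f_c = 5} kHz this is 35.8 microseconds
#' (36 microseconds at microsecond precision).
#'
#' @param f_c Filter corner frequency in Hz (> 0).
#' @return Dead time in seconds.
#' @examples
#' dead_time(5000) * 1e6 # 35.8 us
#' @export
dead_time <- function(f_c) {
  stopifnot(is.numeric(f_c), all(f_c > 0))
  0.179 / f_c
}

#' Idealize a trace by half-amplitude threshold crossing
#'
#' Detects openings and closings as crossings of the 50% level between the
#' closed baseline and the open amplitude. The sampled trace is first
#' interpolated with a cubic spline (`oversample`-fold, default 10x) and
#' crossing times are located on the interpolated trace, so event durations
#' have sub-sample resolution. A sample exactly at threshold is assigned to
#' the state of the preceding sample.
#'
#' Long traces are processed in chunks so memory stays bounded.
#'
#' @param trace A `sampled_trace` (or tibble with `time`, `current` and an
#'   `f_s` attribute).
#' @param i_open Open-channel amplitude in pA.
#' @param baseline Closed-level current in pA (default 0).
#' @param oversample Spline oversampling factor (default 10).
#' @return An `event_table`: tibble with columns `class` (`"open"` /
#'   `"closed"`, alternating), `start` (s), `duration` (s), `amplitude`
#'   (mean current of the event's samples, pA; `NA` for events shorter than
#'   one sample), with attributes `f_s`, `f_c`.
#' @export
idealize_half_amplitude <- function(trace, i_open, baseline = 0,
                                    oversample = 10) {
  stopifnot(is.data.frame(trace), nrow(trace) >= 2, i_open != baseline)
  f_s <- attr(trace, "f_s")
  if (is.null(f_s)) f_s <- 1 / median(diff(trace$time))
  thr <- (baseline + i_open) / 2
  up <- i_open > baseline # TRUE: open lies above threshold

  tt <- trace$time
  yy <- trace$current
  n <- length(yy)
  fine_dt <- 1 / (f_s * oversample)

  chunk <- 2^20
  starts <- seq(1L, n, by = chunk)
  cross_times <- vector("list", length(starts))
  first_state <- NULL
  last_above <- NULL # threshold state of the final fine sample of prev chunk
  for (ci in seq_along(starts)) {
    i0 <- starts[ci]
    i1 <- min(n, i0 + chunk - 1L)
    # extend by 3 samples each side for spline context
    e0 <- max(1L, i0 - 3L)
    e1 <- min(n, i1 + 3L)
    xout <- seq(tt[i0], tt[i1], by = fine_dt)
    sp <- spline(tt[e0:e1], yy[e0:e1], xout = xout, method = "fmm")
    above <- sp$y > thr
    # ties: value exactly at threshold keeps the previous state
    eq <- sp$y == thr
    if (any(eq)) {
      for (k in which(eq)) {
        above[k] <- if (k > 1) above[k - 1] else !is.null(last_above) && last_above
      }
    }
    if (ci == 1) first_state <- above[1]
    prev <- c(if (is.null(last_above)) above[1] else last_above,
              above[-length(above)])
    flip <- which(above != prev)
    if (length(flip)) {
      # linear interpolation between fine samples for the crossing instant
      y1 <- c(NA, sp$y[-length(sp$y)])[flip]
      # crossing between fine sample (flip-1) and flip; for flip == 1 the
      # previous fine sample lives in the prior chunk: use its stored y
      t2 <- sp$x[flip]
      y2 <- sp$y[flip]
      t1 <- t2 - fine_dt
      if (any(flip == 1) && !is.null(last_fine_y <- attr(last_above, "y"))) {
        y1[flip == 1] <- last_fine_y
      }
      frac <- (thr - y1) / (y2 - y1)
      frac[!is.finite(frac)] <- 0.5
      frac <- pmin(1, pmax(0, frac))
      cross_times[[ci]] <- t1 + frac * fine_dt
    }
    la <- above[length(above)]
    attr(la, "y") <- sp$y[length(sp$y)]
    last_above <- la
  }
  crossings <- sort(unlist(cross_times))

  t_start <- tt[1] - 0.5 / f_s
  t_end <- tt[n] + 0.5 / f_s
  bounds <- c(t_start, crossings, t_end)
  cls0 <- if (xor(first_state, !up)) "open" else "closed"
  classes <- rep(c(cls0, if (cls0 == "open") "closed" else "open"),
                 length.out = length(bounds) - 1)
  ev <- tibble::tibble(
    class = classes,
    start = bounds[-length(bounds)],
    duration = diff(bounds)
  )
  # drop zero-length artefacts from coincident crossings
  ev <- ev[ev$duration > 0, ]
  ev <- collapse_same_class(ev)
  ev$amplitude <- event_mean_amplitude(ev, tt, yy)
  new_event_table(ev, f_s = f_s, f_c = attr(trace, "f_c"))
}

# merge consecutive events of equal class (can arise after dropping
# zero-length events or after censoring)
collapse_same_class <- function(ev) {
  if (nrow(ev) < 2) return(ev)
  grp <- cumsum(c(1L, ev$class[-1] != ev$class[-nrow(ev)]))
  ev |>
    dplyr::mutate(.grp = grp) |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(class = dplyr::first(.data$class),
                     start = dplyr::first(.data$start),
                     duration = sum(.data$duration), .groups = "drop") |>
    dplyr::select(-".grp") |>
    dplyr::select("class", "start", "duration")
}

event_mean_amplitude <- function(ev, tt, yy) {
  if (nrow(ev) == 0) return(numeric())
  cs <- cumsum(yy)
  lo <- findInterval(ev$start, tt) # samples strictly inside the event
  hi <- findInterval(ev$start + ev$duration, tt)
  cnt <- hi - lo
  s <- cs[pmax(hi, 1)] - ifelse(lo >= 1, cs[pmax(lo, 1)], 0)
  ifelse(cnt > 0, s / cnt, NA_real_)
}

new_event_table <- function(x, f_s = NA_real_, f_c = NA_real_) {
  attr(x, "f_s") <- f_s
  attr(x, "f_c") <- f_c
  class(x) <- c("event_table", setdiff(class(x), "event_table"))
  x
}

#' Censor events shorter than the dead time
#'
#' Events briefer than `T_d` cannot be resolved by the filter and are
#' treated as missed: each such event is removed and its flanking same-class
#' events are merged into one (durations summed, including the removed
#' event's, so total record time is conserved). Removal proceeds
#' shortest-event-first, which makes the operation deterministic and
#' idempotent. No surviving event is shorter than `T_d` (except a record
#' reduced to a single event).
#'
#' @param events An `event_table` (alternating classes).
#' @param T_d Dead time in seconds (see [dead_time()]).
#' @return A censored `event_table` (the `amplitude` column, if present, is
#'   dropped: censoring changes event extents).
#' @export
apply_dead_time <- function(events, T_d) {
  stopifnot(is.data.frame(events), T_d >= 0)
  if (nrow(events) == 0 || T_d == 0) return(events)
  code <- as.integer(factor(events$class, levels = c("closed", "open")))
  res <- dead_time_censor_cpp(code, events$duration, T_d)
  out <- tibble::tibble(
    class = c("closed", "open")[res$class],
    duration = res$duration
  )
  t0 <- events$start[1]
  out$start <- t0 + cumsum(c(0, out$duration[-nrow(out)]))
  out <- out[, c("class", "start", "duration")]
  new_event_table(out, f_s = attr(events, "f_s"), f_c = attr(events, "f_c"))
}

#' Annotate events with their mean current amplitude
#'
#' Recomputes each event's mean sample current from the trace (censoring
#' merges events, so amplitudes must be re-derived). Partial closures that
#' never reach the baseline — merged fast-flicker runs — retain elevated
#' amplitudes and can thereby be distinguished from full closures.
#'
#' @param events An `event_table` (e.g. after [apply_dead_time()]).
#' @param trace The `sampled_trace` the events were detected on.
#' @return The event table with an `amplitude` column (pA; `NA` for events
#'   shorter than one sample).
#' @export
annotate_amplitudes <- function(events, trace) {
  stopifnot(is.data.frame(events), is.data.frame(trace))
  events$amplitude <- event_mean_amplitude(events, trace$time, trace$current)
  events
}

#' Open probability from an event table
#'
#' \eqn{P_o = \sum d_o / (\sum d_o + \sum d_c)}: total open time over total
#' time.
#'
#' @param events An `event_table` (>= 1 event).
#' @return Scalar in `[0, 1]`.
#' @export
open_probability <- function(events) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0) abort("empty event table")
  open_fraction(events)
}
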