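#' Plot a sampled current trace
#'
#' Line plot of current against time; traces longer than `max_points`
#' samples are min/max-decimated so openings remain visible.
#'
#' @param object A `sampled_trace`.
#' @param max_points Decimation budget.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sampled_trace <- function(object, max_points = 2e5, ...) {
  d <- object
  n <- nrow(d)
  if (n > max_points) {
    grp <- ceiling(seq_len(n) / ceiling(n / (max_points / 2)))
    d <- d |>
      dplyr::mutate(.g = grp) |>
      dplyr::group_by(.data$.g) |>
      dplyr::summarise(time = c(min(.data$time), max(.data$time)),
                       current = c(min(.data$current), max(.data$current)),
                       .groups = "drop")
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$current)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "Time (s)", y = "Current (pA)")
}

#' Plot an all-points amplitude histogram
#'
#' @param object An `amplitude_histogram`.
#' @param log_y Plot density on a log scale (reveals the flicker tails)?
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.amplitude_histogram <- function(object, log_y = FALSE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$mid, .data$density)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Current (pA)", y = "Density (per bin)")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a log-binned dwell-time histogram
#'
#' Square-root counts against log10 duration, the standard display in
#' which each exponential component forms a peak at its time constant;
#' optionally overlays a fitted [fit_dwell_mixture()] density.
#'
#' @param object A `dwell_histogram`.
#' @param mixture Optional `exp_mixture` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dwell_histogram <- function(object, mixture = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(log10(.data$mid), sqrt(.data$count))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "log10 duration (s)", y = expression(sqrt(count)))
  if (!is.null(mixture)) {
    n <- sum(object$count)
    bpd <- attr(object, "bins_per_decade")
    grid <- tibble::tibble(l = seq(min(object$log10_left),
                                   max(object$log10_right), length.out = 200))
    # counts per log bin for a shifted-exponential mixture
    dens <- purrr::map_dbl(grid$l, function(l) {
      t <- 10^l
      sum(mixture$components$weight / mixture$components$tau *
            exp(-pmax(t - mixture$T_d, 0) / mixture$components$tau)) *
        t * log(10) / bpd * n
    })
    grid$y <- sqrt(dens)
    p <- p + ggplot2::geom_line(data = grid, ggplot2::aes(.data$l, .data$y),
                                colour = "steelblue")
  }
  p
}

#' Plot a Boltzmann conductance-voltage fit
#'
#' @param object A `boltzmann_fit`.
#' @param ... Unused.
#' @return A ggplot with the data points and the fitted curve.
#' @export
autoplot.boltzmann_fit <- function(object, ...) {
  kt <- thermal_voltage_mV()
  vv <- seq(min(object$fitted$voltage), max(object$fitted$voltage),
            length.out = 200)
  curve <- tibble::tibble(
    voltage = vv,
    conductance = object$g_max / (1 + exp(-object$z * (vv - object$v_half) / kt))
  )
  ggplot2::ggplot(object$fitted,
                  ggplot2::aes(.data$voltage, .data$conductance)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(x = "Voltage (mV)", y = "Conductance")
}

#' Plot the convergence of an extended-beta fit
#'
#' Best (accepted) merit against iteration; non-increasing by
#' construction.
#'
#' @param object A `scheme1_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scheme1_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$iteration, .data$best)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Iteration", y = expression(chi^2 ~ "(best)"))
}
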