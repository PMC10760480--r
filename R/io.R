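#' Read and write sampled traces as tabular text
#'
#' The canonical interchange format is plain text: a header block of
#' `# key: value` lines declaring at least `f_s`, `f_c` and `V`, followed by
#' two tab-separated columns `time_s` and `current_pA`. `read_trace()`
#' errors, naming the field, if a required header entry is missing.
#'
#' @param trace A `sampled_trace`.
#' @param path File path.
#' @return `read_trace()` returns a `sampled_trace`; `write_trace()` returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace), all(c("time", "current") %in% names(trace)))
  hdr <- c(
    sprintf("# f_s: %.10g", attr(trace, "f_s")),
    sprintf("# f_c: %.10g", attr(trace, "f_c")),
    sprintf("# V: %.10g", attr(trace, "V")),
    sprintf("# noise_sigma: %.10g", attr(trace, "noise_sigma")),
    "time_s\tcurrent_pA"
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(sprintf("%.9g\t%.7g", trace$time, trace$current), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  hdr <- lines[is_hdr]
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- m[3]
  }
  for (field in c("f_s", "f_c", "V")) {
    if (is.null(kv[[field]])) {
      abort(paste0("trace file is missing required header field '", field, "'"))
    }
  }
  body <- lines[!is_hdr]
  body <- body[!grepl("^time_s", body)]
  body <- body[nzchar(body)]
  if (length(body) == 0) abort("trace file has no samples")
  parts <- strsplit(body, "\t", fixed = TRUE)
  cur <- as.numeric(vapply(parts, `[`, character(1), 2))
  tm <- as.numeric(vapply(parts, `[`, character(1), 1))
  out <- new_sampled_trace(cur,
                           f_s = as.numeric(kv$f_s), f_c = as.numeric(kv$f_c),
                           noise_sigma = if (is.null(kv$noise_sigma)) NA_real_
                                         else as.numeric(kv$noise_sigma),
                           V = as.numeric(kv$V))
  out$time <- tm
  out
}

#' Write an event or burst table as tabular text
#'
#' @param x An `event_table` or `burst_table`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Default analysis configuration
#'
#' The resolved parameter set of [run_pipeline()]: one global `seed`
#' (expanded into independent per-stage seeds), the simulated recording
#' condition, and per-stage analysis parameters. Any supplied option must
#' match a known key — unknown keys raise an error before any stage runs.
#'
#' @param ... Named overrides of the defaults (nested lists are merged).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out_dir = NULL,
    recording = list(
      scheme1 = list(alpha_o = 1500, alpha_c = 27, beta_o = 22500,
                     beta_c = 600, gamma_o = 127500, gamma_c = 30000),
      i_open = 10, f_s = 50000, f_c = 5000, noise_sigma = 1,
      duration = 10, V = NA_real_
    ),
    idealize = list(oversample = 10),
    dwell = list(bins_per_decade = 10, n_closed_components = 2,
                 n_open_components = 1),
    histogram = list(bin_width_sd = 0.2, pad = 0.005),
    betafit = list(enabled = FALSE, topology = "3c1o", iterations = 100,
                   n_sims = 10, record_s = 10),
    macroscopic = list(enabled = FALSE, z = 0.65, v_half = -20,
                       n_channels = 100, g = 100, v_rev = 0,
                       noise_frac = 0.02)
  )
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  cfg <- merge_config(defaults, over, path = "")
  class(cfg) <- "run_config"
  cfg
}

merge_config <- function(base, over, path = "") {
  if (length(over) == 0) return(base)
  nm <- names(over)
  if (is.null(nm) || any(!nzchar(nm))) abort("config overrides must be named")
  for (k in nm) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base)) abort(paste0("unknown config key: '", full, "'"))
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], over[[k]], full)
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

# one global seed expanded into independent per-stage streams
stage_seed <- function(seed, stage) {
  offsets <- c(path = 11L, noise = 23L, betafit = 37L, macroscopic = 53L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full single-channel analysis pipeline
#'
#' Composes every stage on a simulated recording: Monte Carlo gating and
#' trace synthesis, half-amplitude idealization with dead-time censoring,
#' open probability, dwell-time mixture fits, critical time and burst
#' segmentation, all-points amplitude histogram, optionally the
#' extended-beta rate fit, and optionally a macroscopic G-V branch
#' (voltage-step family, Boltzmann fit). If `out_dir` is set in the config,
#' the trace, event and burst tables, the resolved configuration and a log
#' are written there.
#'
#' @param config A [run_config()] (or named list of overrides).
#' @return A named list of results: `truth` (manifest), `trace`, `events`,
#'   `p_open`, `dwell` (mixtures), `t_c`, `bursts`, `histogram`, and
#'   optionally `betafit` and `macroscopic`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  cfg <- config
  log <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  rc <- cfg$recording
  p1 <- do.call(scheme1_params, rc$scheme1)
  scheme <- as_gating_scheme(p1, i_open = rc$i_open, V = 0)
  note("simulate: %g s of gating, f_s = %g Hz, f_c = %g Hz",
       rc$duration, rc$f_s, rc$f_c)
  path <- stage("simulate",
    simulate_state_path(scheme, rc$duration,
                        seed = stage_seed(cfg$seed, "path")))
  trace <- stage("render",
    render_trace(path, f_s = rc$f_s, f_c = rc$f_c,
                 noise_sigma = rc$noise_sigma,
                 seed = stage_seed(cfg$seed, "noise"), V = rc$V))
  out$truth <- list(scheme1 = rc$scheme1, seed = cfg$seed,
                    p_open_true = predict_open_probability(p1),
                    open_fraction_realized = open_fraction(path),
                    n_events_true = nrow(path))
  out$trace <- trace

  T_d <- dead_time(rc$f_c)
  ev <- stage("idealize",
    idealize_half_amplitude(trace, i_open = rc$i_open,
                            oversample = cfg$idealize$oversample))
  ev <- apply_dead_time(ev, T_d)
  out$events <- ev
  out$p_open <- open_probability(ev)
  note("idealize: %d events after dead-time censoring, P_o = %.3f",
       nrow(ev), out$p_open)

  dw <- cfg$dwell
  closed <- ev$duration[ev$class == "closed"]
  open <- ev$duration[ev$class == "open"]
  out$dwell <- stage("dwell", list(
    closed_hist = log_binned_histogram(closed, dw$bins_per_decade),
    open_hist = log_binned_histogram(open, dw$bins_per_decade),
    closed_mix = fit_dwell_mixture(closed, dw$n_closed_components, T_d),
    open_mix = fit_dwell_mixture(open, dw$n_open_components, T_d)
  ))
  tc <- stage("critical_time", critical_time_from_mixture(out$dwell$closed_mix))
  out$t_c <- tc$t_c
  out$bursts <- stage("bursts", segment_bursts(ev, tc$t_c))
  note("bursts: t_c = %.4g s, %d bursts", tc$t_c, nrow(out$bursts))

  hs <- cfg$histogram
  segs <- stage("histogram",
    select_bursts_for_histogram(ev, trace, tc$t_c, pad = hs$pad))
  if (length(segs) == 0) segs <- list(trace$current)
  out$histogram <- all_points_histogram(
    segs, bin_width = hs$bin_width_sd * rc$noise_sigma)

  if (isTRUE(cfg$betafit$enabled)) {
    bf <- cfg$betafit
    note("betafit: topology %s, %d iterations x %d sims",
         bf$topology, bf$iterations, bf$n_sims)
    init <- stage("betafit",
      initial_rates_from_trace(ev, f_c = rc$f_c, topology = bf$topology))
    out$betafit <- stage("betafit", fit_extended_beta(
      out$histogram, init = init, topology = bf$topology,
      i_open = rc$i_open, f_s = rc$f_s, f_c = rc$f_c,
      noise_sigma = rc$noise_sigma,
      config = beta_fit_config(iterations = bf$iterations,
                               n_sims = bf$n_sims, record_s = bf$record_s,
                               seed = stage_seed(cfg$seed, "betafit"))))
    note("betafit: chi2 = %.5g", out$betafit$chi2)
  }

  if (isTRUE(cfg$macroscopic$enabled)) {
    mc <- cfg$macroscopic
    steps <- stage("macroscopic", generate_macroscopic(
      truth = list(z = mc$z, v_half = mc$v_half),
      n_channels = mc$n_channels, g = mc$g, v_rev = mc$v_rev,
      noise_sigma = 0, seed = stage_seed(cfg$seed, "macroscopic")))
    i_max <- max(abs(attr(steps, "truth_manifest")$steady_state_current))
    steps <- generate_macroscopic(
      truth = list(z = mc$z, v_half = mc$v_half),
      n_channels = mc$n_channels, g = mc$g, v_rev = mc$v_rev,
      noise_sigma = mc$noise_frac * i_max,
      seed = stage_seed(cfg$seed, "macroscopic"))
    iv <- measure_steady_state(steps)
    gv <- conductance_from_iv(iv, v_rev = mc$v_rev)
    bfit <- stage("macroscopic", fit_boltzmann(gv))
    out$macroscopic <- list(steps = iv, gv = gv, boltzmann = bfit)
    note("macroscopic: fitted z = %.3f, V1/2 = %.2f mV", bfit$z, bfit$v_half)
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trace(trace, file.path(cfg$out_dir, "trace.txt"))
    write_events(ev, file.path(cfg$out_dir, "events.txt"))
    write_events(out$bursts, file.path(cfg$out_dir, "bursts.txt"))
    cfg_plain <- unclass(cfg)
    cfg_plain$out_dir <- as.character(cfg_plain$out_dir)
    yaml::write_yaml(cfg_plain, file.path(cfg$out_dir, "config.yaml"))
    yaml::write_yaml(out$truth, file.path(cfg$out_dir, "truth.yaml"))
    writeLines(log, file.path(cfg$out_dir, "run.log"))
  }
  out$log <- log
  out$config <- cfg
  out
}
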