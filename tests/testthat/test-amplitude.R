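test_that("all-points histograms conserve counts and locate the closed peak", {
  set.seed(81)
  x <- rnorm(50000, 0.3, 0.5)
  h <- all_points_histogram(x, bin_width = 0.1)
  expect_equal(sum(h$count), length(x))
  expect_equal(sum(h$density), 1)
  # pure baseline noise: after alignment the peak sits at 0 within a bin
  expect_lt(abs(h$mid[which.max(h$count)]), 0.1)
  expect_lt(abs(attr(h, "align_shift") - 0.3), 0.05)
  # histogram mean equals the direct sample mean (modulo binning)
  h2 <- all_points_histogram(x, bin_width = 0.1, align = FALSE)
  expect_equal(sum(h2$mid * h2$density), mean(x), tolerance = 0.01)
  expect_error(all_points_histogram(numeric()), "no samples")
})

test_that("burst selection pads segments and re-centers the baseline", {
  # no bursts: empty selection
  ev0 <- make_events("closed", 0.1)
  tr0 <- render_trace(ev0 |> dplyr::mutate(amplitude = 0),
                      f_s = 50000, f_c = Inf, noise_sigma = 0)
  expect_length(select_bursts_for_histogram(ev0, tr0, 1e-3), 0)
  # one burst, no padding: segment covers the burst extent
  path <- make_events(c("closed", "open", "closed", "open", "closed"),
                      c(0.02, 0.004, 0.001, 0.003, 0.02))
  path$amplitude <- ifelse(path$class == "open", 10, 0)
  tr <- render_trace(path, f_s = 50000, f_c = Inf, noise_sigma = 0)
  seg <- select_bursts_for_histogram(path, tr, t_c = 5e-3, pad = 0)
  expect_length(seg, 1)
  expect_equal(length(seg[[1]]) / 50000, 0.008, tolerance = 0.01)
  # baseline-offset trace: padded segments let alignment recover the offset
  trb <- tr
  trb$current <- trb$current + 1.7 + rnorm(nrow(trb), sd = 0.3)
  segb <- select_bursts_for_histogram(path, trb, t_c = 5e-3, pad = 0.015)
  hb <- all_points_histogram(segb, bin_width = 0.1)
  expect_lt(abs(attr(hb, "align_shift") - 1.7), 0.2)
  expect_lt(abs(hb$mid[which.max(hb$count)]), 0.11)
})

test_that("simulated histograms reach the two-Gaussian and averaging limits", {
  # slow gating (rates << f_c): two Gaussian peaks with areas proportional
  # to the realized occupancies
  sch <- two_state(50, 50)
  path <- simulate_state_path(sch, 30, seed = 82)
  tr <- render_trace(path, f_s = 50000, f_c = 5000, noise_sigma = 1,
                     seed = 83)
  h <- all_points_histogram(tr$current, bin_width = 0.2, align = FALSE)
  open_area <- sum(h$density[h$mid > 5])
  expect_equal(open_area, open_fraction(path), tolerance = 0.02)
  # fast gating (rates >> f_c): single peak at P_O * i_open
  fast <- scheme1_params(1e5, 1e5, 127500, 30000, 2e5, 5e4)
  po <- predict_open_probability(fast)
  hf <- simulate_histogram(fast, i_open = 10, record_s = 5, seed = 84,
                           noise_sigma = 1)
  m <- sum(hf$mid * hf$density)
  expect_equal(m, po * 10, tolerance = 0.01)
  # a single prominent mode, not one peak per conductance level
  sm <- as.numeric(stats::filter(hf$count, rep(1 / 5, 5), sides = 2))
  k <- which(!is.na(sm))
  sm <- sm[k]
  n_modes <- sum(sm > c(-Inf, sm[-length(sm)]) & sm >= c(sm[-1], -Inf) &
                   sm > 0.2 * max(sm))
  expect_equal(n_modes, 1)
  # degenerate: always open, no noise -> all mass in the bin at i_open
  always_open <- gating_scheme(
    states = data.frame(label = c("O", "C"), class = c("open", "closed"),
                        amplitude = c(10, 0)),
    rates = data.frame(from = c("O", "C"), to = c("C", "O"),
                       k0 = c(1e-9, 1e9), z = 0)
  )
  h0 <- simulate_histogram(always_open, i_open = 10, record_s = 0.1,
                           noise_sigma = 0, seed = 85)
  expect_equal(sum(h0$density[abs(h0$mid - 10) < 0.1]), 1)
})

test_that("noise and filtering preserve the mean current of the gating path", {
  set.seed(86)
  for (i in 1:3) {
    p <- random_scheme1()
    sch <- as_gating_scheme(p, i_open = 8)
    path <- simulate_state_path(sch, 4)
    tr <- render_trace(path, f_s = 50000, f_c = 5000, noise_sigma = 0.8)
    h <- all_points_histogram(tr$current, bin_width = 0.16, align = FALSE)
    # histogram mean against the realized open fraction of the truth path
    expect_lt(abs(sum(h$mid * h$density) - open_fraction(path) * 8) / 8,
              0.005)
  }
})

test_that("histogram distance is a symmetric divergence on shared bins", {
  set.seed(87)
  h1 <- all_points_histogram(rnorm(20000), bin_width = 0.2, align = FALSE)
  expect_equal(histogram_distance(h1, h1), 0)
  h2 <- simulate_histogram(ref_params(), record_s = 1, seed = 88,
                           breaks_from = h1)
  expect_equal(histogram_distance(h1, h2), histogram_distance(h2, h1))
  expect_gt(histogram_distance(h1, h2), 0)
  h3 <- all_points_histogram(rnorm(20000), bin_width = 0.3, align = FALSE)
  expect_error(histogram_distance(h1, h3), "bins")
  # rebinning redistributes counts without losing any
  h4 <- rebin_histogram(h3, h1)
  expect_equal(nrow(h4), nrow(h1))
  expect_lt(abs(sum(h4$count) - sum(h3$count)) / sum(h3$count), 0.05)
})

test_that("chi-square rises as simulated rates leave the generating truth", {
  exp_hist <- simulate_histogram(ref_params(), record_s = 5, seed = 91)
  chis <- purrr::map_dbl(c(0.2, 1, 5), function(f) {
    r <- ref_rates
    r[["gamma_c"]] <- r[["gamma_c"]] * f
    mean(purrr::map_dbl(1:3, function(i) {
      histogram_distance(
        simulate_histogram(r, record_s = 5, seed = 92 + i,
                           breaks_from = exp_hist),
        exp_hist)
    }))
  })
  expect_lt(chis[2], chis[1])
  expect_lt(chis[2], chis[3])
})
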