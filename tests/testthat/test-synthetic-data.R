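test_that("dwell sampling is exponential with the total exit rate", {
  sch <- ref_scheme()
  set.seed(5)
  d <- sample_dwell(sch, "O", n = 1e5)
  # mean matches 1/(sum of exit rates) = 32.65 us
  expect_equal(mean(d), 1 / 30627, tolerance = 0.01)
  # distributional check against Exponential(sum k)
  ks <- suppressWarnings(stats::ks.test(d[1:1e4], stats::pexp, rate = 30627))
  expect_gt(ks$p.value, 0.01)
  expect_error(sample_dwell(sch, "nope"), "exits|unknown")
})

test_that("state paths are reproducible, alternating, and truncated", {
  sch <- ref_scheme()
  expect_equal(nrow(simulate_state_path(sch, 0)), 0)
  p1 <- simulate_state_path(sch, 0.05, seed = 9)
  p2 <- simulate_state_path(sch, 0.05, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1$duration > 0))
  expect_true(all(p1$state[-1] != p1$state[-nrow(p1)]))
  expect_equal(sum(p1$duration), 0.05)
  expect_equal(p1$start, cumsum(c(0, p1$duration[-nrow(p1)])))
})

test_that("long-run occupancy converges to the steady state", {
  sch <- ref_scheme()
  path <- simulate_state_path(sch, 60, seed = 11)
  expect_equal(open_fraction(path), 0.7813, tolerance = 0.02)
  # per-state empirical dwell means match 1/(exit rate)
  mean_open <- mean(path$duration[path$class == "open" &
                                    path$start > 0 &
                                    path$start + path$duration < 60])
  expect_equal(mean_open, 1 / 30627, tolerance = 0.01)
})

test_that("the Gaussian filter kernel has the prescribed width and unit gain", {
  expect_equal(gaussian_filter_sigma(5000), sqrt(log(2)) / (2 * pi * 5000))
  expect_equal(gaussian_filter_sigma(5000) * 1e6, 26.5, tolerance = 1e-3)
  h <- gaussian_filter_kernel(5000, 50000)
  expect_equal(sum(h), 1)
  expect_equal(h, rev(h))
})

test_that("rendering preserves the mean and hits the requested noise level", {
  sch <- two_state(50, 50)
  path <- simulate_state_path(sch, 2, seed = 13)
  # noiseless unfiltered rendering is exactly two-level
  tr0 <- render_trace(path, f_s = 50000, f_c = Inf, noise_sigma = 0)
  expect_true(all(tr0$current %in% c(0, 10)))
  # unit DC gain: filtering leaves the mean unchanged
  tr1 <- render_trace(path, f_s = 50000, f_c = 5000, noise_sigma = 0)
  expect_equal(mean(tr1$current), mean(tr0$current), tolerance = 1e-9)
  # post-filter closed-level SD matches noise_sigma; filtering shrinks the
  # white input noise
  flat <- tibble::tibble(class = "closed", state = "C", amplitude = 0,
                         start = 0, duration = 2)
  trn <- render_trace(flat, f_s = 50000, f_c = 5000, noise_sigma = 0.8,
                      seed = 3)
  expect_equal(sd(trn$current), 0.8, tolerance = 0.02)
  h <- gaussian_filter_kernel(5000, 50000)
  pre_sd <- 0.8 / sqrt(sum(h^2))
  expect_lt(sd(trn$current), pre_sd)
  # sampling slower than twice the corner frequency is rejected
  expect_error(render_trace(path, f_s = 9000, f_c = 5000), "twice")
})

test_that("macroscopic step families follow N * P_O * g * (V - Vrev)", {
  # ohmic limit: P_O == 1 via enormous opening rates
  sat <- scheme1_params(1e9, 1, 1e9, 1, 1e9, 1)
  steps <- generate_macroscopic(sat, n_channels = 10, g = 100, v_rev = -10,
                                noise_sigma = 0)
  iv <- measure_steady_state(steps)
  expect_equal(iv$current, 10 * 100 * (iv$voltage + 10) / 1000,
               tolerance = 1e-6)
  # Boltzmann truth: current vanishes at the reversal potential
  steps <- generate_macroscopic(list(z = 0.65, v_half = -20),
                                voltages = c(-30, 0, 30), v_rev = 0,
                                n_channels = 50, g = 90, noise_sigma = 0)
  iv <- measure_steady_state(steps)
  expect_equal(iv$current[iv$voltage == 0], 0)
  man <- attr(steps, "truth_manifest")
  expect_equal(man$open_probability,
               1 / (1 + exp(-0.65 * (c(-30, 0, 30) + 20) / thermal_voltage_mV())))
  # reproducible from the seed
  s1 <- generate_macroscopic(list(z = 0.65, v_half = -20), noise_sigma = 2,
                             seed = 4)
  s2 <- generate_macroscopic(list(z = 0.65, v_half = -20), noise_sigma = 2,
                             seed = 4)
  expect_identical(s1$current, s2$current)
})
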