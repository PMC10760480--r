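test_that("rate laws evaluate the exponential voltage dependence", {
  # zero voltage and zero charge leave the rate untouched
  expect_equal(rate_at_voltage(rate_law(875.09, -0.7), 0), 875.09)
  expect_equal(rate_at_voltage(rate_law(100, 0), 130), 100)
  # direct evaluation with kT/e0 at 296 K as oracle
  kt <- 1000 * 1.380649e-23 * 296 / 1.602176634e-19
  expect_equal(rate_at_voltage(rate_law(875.09, -0.13178), 70),
               875.09 * exp(-0.13178 * 70 / kt))
  expect_equal(round(rate_at_voltage(rate_law(875.09, -0.13178), 70)), 610)
  # log-linearity in V is exact
  law <- rate_law(321.4, 0.37)
  v1 <- 43; v2 <- -91
  expect_equal(log(rate_at_voltage(law, v1)) - log(rate_at_voltage(law, v2)),
               0.37 * (v1 - v2) / thermal_voltage_mV())
})

test_that("transition probabilities normalize and scale-invariantly branch", {
  sch <- ref_scheme()
  # single exit: probability one
  p_cs <- transition_probabilities(sch, "Cs", 0)
  expect_equal(p_cs$p, 1)
  expect_equal(p_cs$to, "O")
  # open state with three exits: hand arithmetic
  p_o <- transition_probabilities(sch, "O", 0)
  expect_equal(sum(p_o$p), 1)
  expect_equal(p_o$p[match(c("Cs", "Cm", "Cf"), p_o$to)],
               c(27, 600, 30000) / 30627)
  # uniform scaling of all exit rates leaves branching unchanged
  scaled <- as_gating_scheme(scheme1_params(1500, 27 * 7, 22500, 600 * 7,
                                            127500, 30000 * 7), 10)
  expect_equal(transition_probabilities(scaled, "O", 0)$p, p_o$p)
  # absorbing state errors
  bad <- gating_scheme(
    states = data.frame(label = c("C", "O"), class = c("closed", "open"),
                        amplitude = c(0, 1)),
    rates = data.frame(from = "C", to = "O", k0 = 5, z = 0)
  )
  expect_error(transition_probabilities(bad, "O", 0), "absorbing")
})

test_that("steady-state occupancy solves the balance equations", {
  # symmetric two-state scheme splits 50/50
  occ <- steady_state_occupancy(two_state(100, 100), 0)
  expect_equal(occ$occupancy, c(0.5, 0.5))
  # reference star rates give the open probability of the closed form
  occ <- steady_state_occupancy(ref_scheme(), 0)
  expect_equal(sum(occ$occupancy), 1)
  expect_equal(occ$occupancy[occ$state == "O"], 0.781, tolerance = 1e-3)
  # occupancies satisfy pi Q = 0 and sum to 1 for random schemes
  set.seed(71)
  for (i in 1:20) {
    p <- random_scheme1()
    sch <- as_gating_scheme(p, 10)
    occ <- steady_state_occupancy(sch, 0)
    expect_equal(sum(occ$occupancy), 1)
    expect_true(all(occ$occupancy >= 0))
    resid <- occ$occupancy %*% scheme_rate_matrix(sch, 0)
    expect_lt(max(abs(resid)), 1e-8)
  }
  # disconnected scheme errors
  disc <- gating_scheme(
    states = data.frame(label = c("A", "B", "C", "D"),
                        class = c("closed", "open", "closed", "open"),
                        amplitude = c(0, 1, 0, 1)),
    rates = data.frame(from = c("A", "B", "C", "D"),
                       to = c("B", "A", "D", "C"),
                       k0 = c(1, 1, 1, 1), z = 0)
  )
  expect_error(steady_state_occupancy(disc, 0), "connected")
})

test_that("closed-form star-scheme open probability matches the null-space oracle", {
  p <- ref_params()
  K <- scheme1_equilibrium_constants(p)
  expect_equal(K$K, c(1500 / 27, 22500 / 600, 127500 / 30000))
  expect_equal(predict_open_probability(p),
               null_space_open_probability(p), tolerance = 1e-12)
  # equal unit equilibrium constants: four equally occupied states
  expect_equal(predict_open_probability(scheme1_params(1, 1, 1, 1, 1, 1)),
               0.25)
  # all closing rates -> 0 drives P_O -> 1
  expect_warning(
    po <- predict_open_probability(scheme1_params(10, 0, 10, 0, 10, 0)),
    "zero")
  expect_equal(po, 1)
})

test_that("net transition charge is the opening/closing difference", {
  expect_equal(total_transition_charge(-0.13178, -0.55262), 0.42084)
  expect_equal(total_transition_charge(0.3, 0.3), 0)
  expect_equal(total_transition_charge(0.2, -0.1),
               -total_transition_charge(-0.1, 0.2))
})

test_that("gating schemes round-trip through the text configuration", {
  sch <- gating_scheme(
    states = data.frame(label = c("C1", "O1"), class = c("closed", "open"),
                        amplitude = c(0, 7.25)),
    rates = data.frame(from = c("C1", "O1"), to = c("O1", "C1"),
                       k0 = c(123.456, 78.9), z = c(0.31, -0.44))
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scheme(sch, path)
  back <- read_scheme(path)
  expect_equal(back$states, sch$states)
  expect_equal(purrr::map_dbl(back$rates$law, "k0"),
               purrr::map_dbl(sch$rates$law, "k0"))
  expect_equal(purrr::map_dbl(back$rates$law, "z"),
               purrr::map_dbl(sch$rates$law, "z"))
})
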