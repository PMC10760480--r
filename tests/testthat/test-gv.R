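test_that("conductance follows Ohm's law with the reversal point flagged", {
  iv <- tibble::tibble(voltage = c(-60, -20, 0, 40, 80),
                       current = 0.5 * (c(-60, -20, 0, 40, 80) - 0))
  g <- conductance_from_iv(iv, v_rev = 0)
  expect_equal(g$conductance[g$voltage != 0], rep(0.5, 4))
  expect_true(is.na(g$conductance[g$voltage == 0]))
  expect_equal(conductance_from_iv(
    tibble::tibble(voltage = 50, current = 0), 0)$conductance, 0)
})

test_that("reversal potential is interpolated from the zero crossing", {
  v <- seq(-40, 40, 20)
  iv <- tibble::tibble(voltage = v, current = 0.8 * (v - 7.5))
  expect_equal(estimate_reversal(iv), 7.5)
  expect_error(estimate_reversal(
    tibble::tibble(voltage = v, current = v + 100)), "zero")
})

test_that("Boltzmann fits invert noiseless curves exactly", {
  kt <- thermal_voltage_mV()
  v <- seq(-130, 130, 20)
  g <- 2.4 / (1 + exp(-0.65 * (v + 20) / kt))
  fit <- fit_boltzmann(tibble::tibble(voltage = v, conductance = g))
  expect_equal(fit$z, 0.65, tolerance = 1e-6)
  expect_equal(fit$v_half, -20, tolerance = 1e-6)
  expect_equal(fit$g_max, 2.4, tolerance = 1e-6)
  # the fitted curve is at half maximum at V1/2 by definition
  gpred <- fit$g_max / (1 + exp(-fit$z * (fit$v_half - fit$v_half) / kt))
  expect_equal(gpred, fit$g_max / 2)
  # steep limit approaches a step at V1/2
  g2 <- 1 / (1 + exp(-8 * (v - 10) / kt))
  fit2 <- fit_boltzmann(tibble::tibble(voltage = v, conductance = g2))
  expect_equal(fit2$z, 8, tolerance = 1e-3)
  expect_lt(max(abs(fit2$fitted$fitted[v <= -30])), 1e-4)
  expect_gt(min(fit2$fitted$fitted[v >= 50]), 0.9999)
  # tidy/glance expose the estimates
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "z"], 0.65, tolerance = 1e-6)
  expect_true(glance(fit)$converged)
})

test_that("activation energies and their differences are consistent", {
  fits <- tibble::tibble(ion = c("Na", "Li", "Cs"),
                         z = c(0.55, 0.65, 0.5),
                         v_half = c(10, -20, 25))
  ae <- activation_energies(fits, reference = "Na")
  expect_equal(ae$delta_g, fits$z * fits$v_half)
  expect_equal(ae$ddg[ae$ion == "Na"], 0)
  expect_equal(ae$delta_g_kj_mol,
               fits$z * fits$v_half * 1e-3 * 96485.33212 / 1000)
  # translation invariance of the differences
  shifted <- ae
  shifted$delta_g <- shifted$delta_g + 42
  expect_equal(shifted$delta_g - shifted$delta_g[1], ae$ddg)
  expect_equal(activation_energies(
    tibble::tibble(ion = "Na", z = 0.7, v_half = 0))$delta_g, 0)
})

test_that("rate-law fits invert noiseless voltage dependence", {
  v <- seq(-50, 110, 20)
  law0 <- rate_law(163.28, -0.55262)
  fit <- fit_rate_voltage(tibble::tibble(voltage = v,
                                         rate = rate_at_voltage(law0, v)))
  expect_equal(fit$k0, 163.28, tolerance = 1e-9)
  expect_equal(fit$z, -0.55262, tolerance = 1e-9)
  # voltage-independent rates give zero charge
  flat <- fit_rate_voltage(tibble::tibble(voltage = v, rate = 500))
  expect_equal(flat$z, 0)
  expect_equal(flat$k0, 500)
  expect_error(fit_rate_voltage(tibble::tibble(voltage = 10, rate = 5)),
               "two distinct")
})

test_that("star-scheme G-V predictions match the steady-state solver per voltage", {
  # measured sodium-condition rate laws
  na <- scheme1_params(
    rate_law(875.09, -0.13178), rate_law(163.28, -0.55262),
    rate_law(6302.1, 0.15402), rate_law(191.277, 0.30446),
    rate_law(83222, 0.021433), rate_law(28800.5, -0.02206)
  )
  v <- seq(-130, 130, 20)
  pred <- predict_gv_from_scheme(na, v)
  expect_equal(max(pred$p_open_norm), 1)
  expect_true(all(diff(pred$p_open) > 0)) # monotone over this range
  for (vv in c(-130, -50, -10, 70, 130)) {
    p_at <- scheme1_params(
      rate_at_voltage(na$alpha_o, vv), rate_at_voltage(na$alpha_c, vv),
      rate_at_voltage(na$beta_o, vv), rate_at_voltage(na$beta_c, vv),
      rate_at_voltage(na$gamma_o, vv), rate_at_voltage(na$gamma_c, vv))
    expect_equal(pred$p_open[pred$voltage == vv],
                 null_space_open_probability(p_at), tolerance = 1e-10)
  }
  # zero charges: flat prediction
  zflat <- scheme1_params(
    rate_law(100, 0), rate_law(50, 0), rate_law(10, 0),
    rate_law(10, 0), rate_law(5, 0), rate_law(5, 0))
  expect_equal(diff(range(predict_gv_from_scheme(zflat, v)$p_open)), 0)
})

test_that("rubidium is predicted to open less than sodium at +70 mV", {
  na <- scheme1_params(
    rate_law(875.09, -0.13178), rate_law(163.28, -0.55262),
    rate_law(6302.1, 0.15402), rate_law(191.277, 0.30446),
    rate_law(83222, 0.021433), rate_law(28800.5, -0.02206))
  rb <- scheme1_params(
    rate_law(123.32, -0.23134), rate_law(213.72, -0.44403),
    rate_law(8294.02, 0.042546), rate_law(210.2, 0.24134),
    rate_law(78027.2, 0.044316), rate_law(36391, -0.11627))
  expect_lt(predict_open_probability(rb, 70),
            predict_open_probability(na, 70))
})
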