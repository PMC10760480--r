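test_that("log-binned histograms conserve counts and peak at tau", {
  set.seed(51)
  d <- rexp(20000, 1 / 5e-3)
  h <- log_binned_histogram(d, bins_per_decade = 10)
  expect_equal(sum(h$count), length(d))
  # the log-transformed exponential density peaks at d = tau
  peak_mid <- h$mid[which.max(h$count)]
  expect_equal(log10(peak_mid), log10(5e-3), tolerance = 0.15)
  expect_equal(nrow(log_binned_histogram(numeric())), 0)
})

test_that("truncated-exponential mixture MLE recovers components", {
  set.seed(52)
  # single component: reduces to the shifted sample mean
  td <- 36e-6
  d1 <- td + rexp(5000, 1 / 5e-3)
  f1 <- fit_dwell_mixture(d1, 1, T_d = td)
  expect_equal(f1$components$tau, mean(d1 - td))
  expect_equal(f1$components$tau, 5e-3, tolerance = 0.05)
  expect_equal(f1$components$weight, 1)
  # two well-separated components at equal weight
  d2 <- td + c(rexp(5000, 1 / 0.1e-3), rexp(5000, 1 / 10e-3))
  f2 <- fit_dwell_mixture(d2, 2, T_d = td)
  expect_true(f2$converged)
  expect_equal(f2$components$tau, c(0.1e-3, 10e-3), tolerance = 0.15)
  expect_equal(f2$components$weight, c(0.5, 0.5), tolerance = 0.1)
  expect_true(all(diff(f2$components$tau) > 0))
  # two components fit strictly better than one on two-component data
  f2a <- fit_dwell_mixture(d2, 1, T_d = td)
  expect_gt(f2$loglik, f2a$loglik)
})

test_that("critical time solves the equal-misclassification equation", {
  tc <- critical_time(1, 1e-3, 1, 100e-3)
  # independent bracketed bisection oracle
  f <- function(t) exp(-t / 1e-3) - (1 - exp(-t / 100e-3))
  lo <- 1e-3; hi <- 100e-3
  for (i in 1:80) {
    m <- (lo + hi) / 2
    if (f(m) > 0) lo <- m else hi <- m
  }
  expect_equal(tc, (lo + hi) / 2, tolerance = 1e-9)
  expect_equal(tc, 3.4e-3, tolerance = 0.01)
  # bound property for comparable component amplitudes
  set.seed(53)
  for (i in 1:25) {
    tf <- 10^runif(1, -5, -2)
    ts <- tf * 10^runif(1, 0.7, 3)
    a <- 10^runif(1, -1, 1)
    t1 <- critical_time(a, tf, a, ts)
    expect_gt(t1, tf); expect_lt(t1, ts)
  }
  t1 <- critical_time(1, 1e-3, 1, 50e-3)
  t2 <- critical_time(1, 3e-3, 1, 150e-3)
  expect_equal(t2 / t1, 3, tolerance = 1e-6)
  expect_error(critical_time(1, 1e-2, 1, 1e-3), "smaller")
})

test_that("burst segmentation splits on long closed gaps", {
  ev <- make_events(
    c("open", "closed", "open", "closed", "open"),
    c(1e-3, 0.5e-3, 2e-3, 50e-3, 3e-3)
  )
  # all gaps below t_c: one burst containing every opening
  b1 <- segment_bursts(ev, t_c = 0.1)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$n_openings, 3)
  expect_equal(b1$length, sum(ev$duration))
  # all gaps at or above t_c: one burst per opening
  b2 <- segment_bursts(ev, t_c = 0.4e-3)
  expect_equal(nrow(b2), 3)
  expect_equal(b2$n_openings, c(1, 1, 1))
  expect_equal(b2$length, c(1e-3, 2e-3, 3e-3))
  # intermediate t_c: the 50-ms gap terminates the first burst
  b3 <- segment_bursts(ev, t_c = 10e-3)
  expect_equal(nrow(b3), 2)
  expect_equal(b3$n_openings, c(2, 1))
  expect_equal(b3$length[1], 3.5e-3)
})

test_that("burst lengths from segmented events match the true path", {
  # bursting scheme: segmentation of the true event list against itself
  sch <- ref_scheme()
  path <- simulate_state_path(sch, 20, seed = 61)
  tc <- 2e-3
  b_true <- segment_bursts(path, tc)
  # idealization-free check: mean burst length from the censored truth path
  ev <- apply_dead_time(
    tibble::tibble(class = path$class, start = path$start,
                   duration = path$duration),
    dead_time(5000))
  b_cens <- segment_bursts(ev, tc)
  expect_equal(mean(b_cens$length), mean(b_true$length), tolerance = 0.05)
})

test_that("burst-length distributions of star-scheme gating are multi-exponential", {
  # rapid-bursting parameterization (strong closing into a long-lived slow
  # state) so thousands of short bursts accumulate in a brief record; burst
  # lengths measured on the ground-truth path
  sch <- as_gating_scheme(scheme1_params(100, 5000, 22500, 600, 127500, 30000))
  path <- simulate_state_path(sch, 25, seed = 62)
  bl <- segment_bursts(path, 1e-3)$length
  expect_gt(length(bl), 2000)
  f1 <- fit_dwell_mixture(bl, 1)
  f2 <- fit_dwell_mixture(bl, 2, init_tau = c(3e-5, 4e-4))
  lrt <- 2 * (f2$loglik - f1$loglik)
  expect_gt(lrt, qchisq(0.999, df = 2))
})
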