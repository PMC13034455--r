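# closed-form decay, DSC amplitude, inversion, slow bleach rate

test_that("closed-form decay has the right endpoints and shape", {
  p <- example_params()
  expect_equal(s1_norm_analytic(0, p), 1)
  plateau <- q_ratio(p) * p$k_gsr / (p$k_dsc + q_ratio(p) * p$k_gsr)
  expect_equal(s1_norm_analytic(1e3, p), plateau)
  t <- seq(0, 5e-3, length.out = 200)
  expect_true(all(diff(s1_norm_analytic(t, p)) <= 0))
  expect_gte(dsc_observed_rate(p), p$k_gsr)
})

test_that("DSC amplitude follows its closed form and monotonicities", {
  expect_equal(dsc_amplitude(kinetic_params(k_ex = 1e7, k_f = 8e7,
                                            k_dsc = 1e4, k_gsr = 1e3)),
               1e4 / (1e4 + 9e3))
  expect_identical(dsc_amplitude(kinetic_params(k_ex = 1e7, k_f = 5.8e8,
                                                k_dsc = 0, k_gsr = 1e3)), 0)
  expect_identical(dsc_amplitude(kinetic_params(k_ex = 1e7, k_f = 5.8e8,
                                                k_dsc = 1e4, k_gsr = 0)), 1)
  base <- example_params()
  up_dsc <- kinetic_params(k_ex = 1e7, k_f = 5.8e8, k_dsc = 2 * base$k_dsc,
                           k_gsr = base$k_gsr)
  up_gsr <- kinetic_params(k_ex = 1e7, k_f = 5.8e8, k_dsc = base$k_dsc,
                           k_gsr = 2 * base$k_gsr)
  up_ex <- kinetic_params(k_ex = 2e7, k_f = 5.8e8, k_dsc = base$k_dsc,
                          k_gsr = base$k_gsr)
  expect_gt(dsc_amplitude(up_dsc), dsc_amplitude(base))
  expect_lt(dsc_amplitude(up_gsr), dsc_amplitude(base))
  expect_gt(dsc_amplitude(up_ex), dsc_amplitude(base))  # higher intensity
  pred <- dsc_prediction(base)
  expect_identical(pred$a_dsc + pred$plateau, 1)
})

test_that("amplitude inversion recovers tau_dsc exactly", {
  # a = 1/2 means k_dsc equals q k_gsr; with q k_gsr = 1e3, tau_dsc = 1 ms
  expect_equal(tau_dsc_from_amplitude(0.5, tau_gsr = 59 / 1e3,
                                      k_ex = 1e7, k_f = 5.8e8),
               1e-3)
  withr::with_seed(31, {
    for (i in 1:20) {
      p <- random_params("wide")
      a <- dsc_amplitude(p)
      tau <- tau_dsc_from_amplitude(a, 1 / p$k_gsr, p$k_ex, p$k_f)
      expect_equal(tau * p$k_dsc, 1, tolerance = 1e-12)
    }
  })
  # measured-amplitude pairing: a_dsc 0.23 with q implied by the instrument
  q <- 55.8
  tau <- tau_dsc_from_amplitude(0.23, 1e-3, k_ex = 1, k_f = q - 1)
  expect_equal(tau * 1e6, 60, tolerance = 0.01)
  expect_error(tau_dsc_from_amplitude(1, 1e-3, 1e7, 5.8e8), "strictly")
  expect_error(tau_dsc_from_amplitude(0.5, -1, 1e7, 5.8e8), "> 0")
})

test_that("slow bleach rate has the correct closed-form limits", {
  # no dark pathway: bleaching scaled by the S1 fraction
  p <- kinetic_params(k_ex = 1e7, k_f = 5.8e8, k_dsc = 0, k_gsr = 1e3,
                      k_SB = 100, k_DB = 500)
  expect_equal(slow_bleach_rate(p, warn_separation = FALSE), 100 / 59)
  # fully dark population bleaches at k_DB
  p2 <- kinetic_params(k_ex = 1e7, k_f = 5.8e8, k_dsc = 1e5, k_gsr = 1e-4,
                       k_SB = 0, k_DB = 50)
  expect_equal(slow_bleach_rate(p2, warn_separation = FALSE), 50,
               tolerance = 1e-2)
  # strong-separation limit (k_SB + k_DB qD)/(q + qD) within 1%
  p3 <- kinetic_params(k_ex = 1e7, k_f = 5.8e8, k_dsc = 2e4, k_gsr = 2e3,
                       k_SB = 20, k_DB = 20)
  lim <- (20 + 20 * q_dark(p3)) / (q_ratio(p3) + q_dark(p3))
  expect_equal(slow_bleach_rate(p3, warn_separation = FALSE), lim,
               tolerance = 0.01)
  expect_warning(
    slow_bleach_rate(kinetic_params(k_ex = 1e7, k_f = 5.8e8, k_dsc = 1e4,
                                    k_gsr = 100, k_SB = 0, k_DB = 200)),
    "separation")
})

test_that("slow bleach rate increases with excitation rate and k_DB", {
  rates_kex <- vapply(c(1e6, 3e6, 1e7, 3e7), function(kex) {
    slow_bleach_rate(kinetic_params(k_ex = kex, k_f = 5.8e8, k_dsc = 1.67e4,
                                    k_gsr = 1e3, k_SB = 100, k_DB = 100),
                     warn_separation = FALSE)
  }, 0)
  expect_true(all(diff(rates_kex) > 0))
  rates_kdb <- vapply(c(0, 50, 100, 200), function(kdb) {
    slow_bleach_rate(kinetic_params(k_ex = 1e7, k_f = 5.8e8, k_dsc = 1.67e4,
                                    k_gsr = 1e3, k_SB = 100, k_DB = kdb),
                     warn_separation = FALSE)
  }, 0)
  expect_true(all(diff(rates_kdb) > 0))
})

test_that("analytic bleach decay matches the stiff ODE beyond the transient", {
  p <- example_params(k_SB = 100, k_DB = 100)
  dur <- 0.1
  decay <- ode_decay(p, dur, n = 1000)
  ana <- bleach_decay_analytic(decay$time, p)
  ana <- ana / ana[1]   # same normalization point as the ODE trace
  expect_lt(max(abs(decay$signal - ana)), 0.02)
  # envelope form: exactly 1 with no bleach channel, single-exponential
  # k_SB/q decay with no dark pathway
  p0 <- example_params()
  t <- seq(0, 0.05, length.out = 100)
  expect_equal(bleach_decay_analytic(t, p0, envelope = TRUE), rep(1, 100))
  p1 <- kinetic_params(k_ex = 1e7, k_f = 5.8e8, k_dsc = 0, k_gsr = 1e3,
                       k_SB = 100)
  expect_equal(bleach_decay_analytic(t, p1), exp(-100 * t / 59))
  expect_equal(bleach_decay_analytic(0, p), 1)
  pred <- bleach_prediction(p)
  expect_equal(pred$a1 + pred$a2, 1)
  expect_identical(pred$rate_S1, 100)
})

test_that("closed-form decay tracks the ODE across random parameter sets", {
  # canonical separation: max deviation well under 1% of the amplitude;
  # stressed separation (fast and slow rates as close as ~20x): bounded by
  # the rapid-equilibrium error, under 2.5%
  check <- function(regime, n_sets, bound) {
    worst <- 0
    for (i in seq_len(n_sets)) {
      p <- random_params(regime)
      a <- dsc_amplitude(p)
      dur <- 10 / dsc_observed_rate(p)
      decay <- ode_decay(p, dur)
      ana <- s1_norm_analytic(decay$time, p) / s1_norm_analytic(decay$time[1], p)
      worst <- max(worst, max(abs(decay$signal - ana)) / a)
    }
    expect_lt(worst, bound)
  }
  withr::with_seed(41, check("paper", 25, 0.01))
  withr::with_seed(43, check("wide", 15, 0.025))
})

test_that("slow eigenvalue matches the fitted ODE slope", {
  withr::with_seed(47, {
    for (i in 1:3) {
      p <- kinetic_params(k_ex = 10^runif(1, 6.5, 7), k_f = 5.8e8,
                          k_dsc = 2e4, k_gsr = 2e3,
                          k_SB = 10^runif(1, 1, 1.5),
                          k_DB = 10^runif(1, 1, 1.5))
      lam <- slow_bleach_rate(p, warn_separation = FALSE)
      expect_gt(dsc_observed_rate(p) / lam, 100)  # separation guard
      dur <- 2 / lam
      decay <- ode_decay(p, dur, n = 400)
      keep <- decay$time > 5 / dsc_observed_rate(p)
      slope <- -coef(lm(log(signal) ~ time,
                        data = decay[keep, ]))[["time"]]
      expect_equal(slope, lam, tolerance = 0.02)
    }
  })
})
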