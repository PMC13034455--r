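# three-state model: excitation rate, equilibrium, ODE integration

test_that("excitation rate follows cross-section times photon flux", {
  expect_identical(excitation_rate(0, 561, 74000), 0)
  expect_equal(excitation_rate(2000, 561, 74000),
               2 * excitation_rate(1000, 561, 74000))
  expect_equal(excitation_rate(5000, 561, 2 * 74000),
               2 * excitation_rate(5000, 561, 74000))
  # direct arithmetic oracle: sigma = 1000 ln10 eps / N_A, flux = I lambda/hc
  sigma <- 1000 * log(10) * 74000 / 6.02214076e23
  flux <- 5000 * 561e-9 / (6.62607015e-34 * 2.99792458e8)
  expect_equal(excitation_rate(5000, 561, 74000), sigma * flux)
  # the confocal kW/cm^2 regime excites at a few MHz
  expect_gt(excitation_rate(5000, 561, 74000), 3e6)
  expect_lt(excitation_rate(5000, 561, 74000), 5e6)
  expect_error(excitation_rate(-1, 561, 74000), "must all be")
})

test_that("bright-pool equilibrium fractions satisfy detailed balance", {
  expect_equal(equilibrium_fractions(kinetic_params(k_ex = 1e7, k_f = 1e7)),
               c(S0 = 0.5, S1 = 0.5))
  fr <- equilibrium_fractions(kinetic_params(k_ex = 1e7, k_f = 5.8e8))
  expect_equal(unname(fr["S1"]), 1 / 59)
  withr::with_seed(11, {
    for (i in 1:10) {
      p <- random_params("wide")
      fr <- equilibrium_fractions(p)
      expect_equal(sum(fr), 1)
      expect_equal(unname(fr["S1"]) * q_ratio(p), 1)
      expect_equal(p$k_f * fr[["S1"]], p$k_ex * fr[["S0"]])
    }
  })
  expect_error(equilibrium_fractions(kinetic_params(k_ex = 0, k_f = 0)),
               "cannot both be zero")
})

test_that("q ratios obey their defining identities", {
  p <- example_params()
  expect_identical(q_ratio(p), q_prime(p) + 1)
  expect_equal(q_dark(p), p$k_dsc / p$k_gsr)
  expect_error(q_prime(kinetic_params(k_ex = 0, k_f = 1e8)), "k_ex > 0")
  expect_error(kinetic_params(k_ex = -1, k_f = 1e8), "non-negative")
})

test_that("two-state system reaches the textbook steady state", {
  p <- kinetic_params(k_ex = 2e7, k_f = 3e8)
  wf <- make_waveform("constant", 5, duration = 1e-6)
  tr <- integrate_model(p, wf, sampling = 1e-9, method = "full")
  tail_rows <- tail(tr, 50)
  expect_equal(mean(tail_rows$S1 / (tail_rows$S0 + tail_rows$S1)),
               p$k_ex / (p$k_ex + p$k_f), tolerance = 1e-6)
  expect_true(all(tr$D == 0) && all(tr$B == 0))
})

test_that("population is conserved and bleaching is monotone", {
  withr::with_seed(21, {
    for (i in 1:5) {
      p <- random_params("paper")
      p$k_SB <- 10^runif(1, 1, 2.5)
      p$k_DB <- 10^runif(1, 1, 2.5)
      wf <- make_waveform("constant", 5, duration = 50e-3)
      tr <- integrate_model(p, wf, sampling = 1e-4, method = "full")
      expect_lt(max(abs(tr$S0 + tr$S1 + tr$D + tr$B - 1)), 1e-9)
      expect_true(all(diff(tr$B) >= -1e-12))
      bright <- tr$S0 + tr$S1 + tr$D
      expect_true(all(diff(bright) <= 1e-12))
    }
  })
})

test_that("no-bleach system conserves the unbleached pool exactly", {
  p <- example_params()
  wf <- make_waveform("constant", 5, duration = 5e-3)
  tr <- integrate_model(p, wf, sampling = 5e-6, method = "full")
  expect_lt(max(abs(tr$S0 + tr$S1 + tr$D - 1)), 1e-9)
  expect_true(all(tr$B == 0))
})

test_that("bright-pool ratio stays in rapid equilibrium once equilibrated", {
  # with fast rates >= 1e6 and slow rates <= 1e5, S1/S0 tracks k_ex/k_f
  grid <- expand.grid(k_ex = c(1e6, 1e7, 1e8), k_gsr = c(1e3, 1e5))
  for (i in seq_len(nrow(grid))) {
    p <- kinetic_params(k_ex = grid$k_ex[i], k_f = 5.8e8, k_dsc = 1e5,
                        k_gsr = grid$k_gsr[i])
    dur <- 20 / dsc_observed_rate(p)
    tr <- integrate_model(p, make_waveform("constant", 5, duration = dur),
                          sampling = dur / 300, method = "full")
    keep <- tr$time > 10 / (p$k_ex + p$k_f)
    ratio <- tr$S1[keep] / tr$S0[keep]
    expect_lt(max(abs(ratio / (p$k_ex / p$k_f) - 1)), 0.01)
  }
})

test_that("reduced integrator agrees with the stiff full system", {
  for (set in reference_parameter_sets()) {
    p <- set$params
    wf <- make_waveform("constant", 5, duration = 10e-3)
    full <- integrate_model(p, wf, sampling = 1e-5, method = "full")
    red <- integrate_model(p, wf, sampling = 1e-5, method = "reduced")
    keep <- full$time > 1e-6
    expect_lt(max(abs(full$S1 - red$S1)[keep]) / max(full$S1), 2e-3)
    expect_lt(max(abs(full$D - red$D)[keep]), 2e-3)
  }
})

test_that("integration spans nine decades of rate scales on reference sets", {
  for (set in reference_parameter_sets()) {
    wf <- make_waveform("constant", 5, duration = 1)
    tr <- integrate_model(set$params, wf, sampling = 1e-2, method = "full")
    expect_lt(max(abs(tr$S0 + tr$S1 + tr$D + tr$B - 1)), 1e-9)
    expect_gt(tail(tr$B, 1), 0)
  }
})

test_that("invalid integration inputs fail loudly", {
  p <- example_params()
  wf <- make_waveform("constant", 5, duration = 1e-3)
  expect_error(integrate_model(p, wf, duration = -1), "duration")
  expect_error(integrate_model(p, wf, sampling = c(-1e-3, 5e-4)),
               "must lie in")
})
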