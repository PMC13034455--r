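# synthetic traces: determinism, noise models, protocols, reference sets

test_that("equal seeds give bitwise-identical traces", {
  p <- example_params(k_SB = 100, k_DB = 30)
  wf <- make_waveform("constant", 5, duration = 5e-3)
  for (kind in c("poisson", "gaussian", "poisson+gaussian")) {
    nz <- noise_model(kind, photons_per_unit_signal = 1e4,
                      gaussian_sd = 0.02, seed = 99)
    tr1 <- simulate_trace(p, wf, sampling = 1e-5, noise = nz)
    tr2 <- simulate_trace(p, wf, sampling = 1e-5, noise = nz)
    expect_identical(tr1$signal, tr2$signal)
  }
  expect_error(noise_model("poisson"), "seed")
})

test_that("noise models preserve the signal expectation", {
  sig <- seq(1, 0.1, length.out = 50)
  for (kind in c("poisson", "gaussian")) {
    reps <- vapply(1:100, function(i) {
      apply_noise(sig, noise_model(kind, photons_per_unit_signal = 1e6,
                                   gaussian_sd = 0.05, seed = i))
    }, numeric(length(sig)))
    se <- apply(reps, 1, sd) / sqrt(ncol(reps))
    dev <- abs(rowMeans(reps) - sig)
    expect_true(all(dev <= 3 * pmax(se, 1e-12)))
  }
  # pure shot noise cannot go negative
  nz <- noise_model("poisson", photons_per_unit_signal = 10, seed = 5)
  expect_true(all(apply_noise(sig, nz) >= 0))
})

test_that("noise-free constant-light trace follows the closed-form decay", {
  p <- example_params()
  wf <- make_waveform("constant", 5, duration = 2e-3)
  tr <- simulate_trace(p, wf, sampling = 2e-6, method = "full")
  keep <- tr$time > 1e-6
  ana <- s1_norm_analytic(tr$time[keep], p)
  expect_lt(max(abs(tr$signal[keep] - ana)) / dsc_amplitude(p), 0.01)
})

test_that("pulse-pair readouts order as FB <= FR <= FL and recover", {
  p <- example_params(k_DB = 0)
  tau_gsr <- 1 / p$k_gsr
  g <- simulate_gsr_experiment(p, dark_times = c(0.1, 1, 10) * tau_gsr)
  expect_true(all(g$FB <= g$FR + 1e-9 & g$FR <= g$FL + 1e-9))
  # full equilibration with no bleaching: FR returns to FL
  far <- simulate_gsr_experiment(p, dark_times = 20 * tau_gsr)
  expect_equal(far$FR, far$FL, tolerance = 1e-3)
  # vanishing dark time: no recovery
  near <- simulate_gsr_experiment(p, dark_times = 1e-3 * tau_gsr)
  expect_equal(near$FR, near$FB, tolerance = 1e-2)
  expect_error(simulate_gsr_experiment(p, dark_times = -1), "positive")
})

test_that("dark-state bleaching leaves recovery incomplete at long dark times", {
  p <- example_params(k_SB = 0, k_DB = 300)
  g <- simulate_gsr_experiment(p, dark_times = 20 / p$k_gsr)
  expect_lt(g$FR, g$FL * 0.995)
})

test_that("bleach family collapses to a single term without a dark pathway", {
  p <- example_params(k_SB = 100, k_DB = 0)
  fam <- simulate_bleach_family(p, intensities = 5, intensity_ref = 5,
                                n_points = 50)
  expect_equal(fam$signal, exp(-100 * fam$time), tolerance = 1e-9)
})

test_that("reference parameter sets encode the published constants", {
  rs <- reference_parameter_sets()
  m <- rs$mcherry_like
  d <- rs$mcherry_d_like
  expect_equal(1 / m$params$k_dsc, 60e-6)
  expect_equal(1 / d$params$k_gsr, 0.5e-3)
  expect_equal(1 / m$params$k_f, 1.72e-9)
  expect_equal(1 / d$params$k_f, 2.22e-9)
  # both sets live in the rapid-equilibrium regime
  for (set in rs) {
    p <- set$params
    expect_gt(p$k_ex + p$k_f, 100 * dsc_observed_rate(p))
    expect_gt(dsc_observed_rate(p),
              10 * slow_bleach_rate(p, warn_separation = FALSE))
  }
  # mCherry-d converts to the dark state with larger amplitude
  expect_gt(dsc_amplitude(d$params), dsc_amplitude(m$params))
})

test_that("trace files round-trip through CSV with sidecar metadata", {
  p <- example_params()
  wf <- make_waveform("rect_pulse_pair", 10, duration = 5e-3,
                      pulse_width = 2e-3, dark_time = 1e-3)
  nz <- noise_model("gaussian", gaussian_sd = 0.01, seed = 3)
  tr <- simulate_trace(p, wf, sampling = 1e-5, noise = nz)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$time, tr$time)
  expect_equal(back$signal, tr$signal)
  meta <- attr(back, "meta")
  expect_equal(meta$protocol, "rect_pulse_pair")
  expect_equal(as.numeric(meta$dark_time_ms), 1)
  expect_equal(as.numeric(meta$seed), 3)
})
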