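# dark-state conversion extraction from continuous traces

test_that("DSC amplitude from a clean trace matches the closed form", {
  rs <- reference_parameter_sets()
  ref <- rs$mcherry_like$params
  wf <- make_waveform("constant", 5, duration = 10e-3)
  # the closed-form amplitude assumes negligible bleaching over the window
  p0 <- kinetic_params(k_ex = ref$k_ex, k_f = ref$k_f, k_dsc = ref$k_dsc,
                       k_gsr = ref$k_gsr)
  tr0 <- simulate_trace(p0, wf, sampling = 5e-6, method = "reduced")
  fit0 <- fit_dsc(tr0, tau_gsr = 1 / p0$k_gsr, k_ex = p0$k_ex, k_f = p0$k_f)
  expect_equal(fit0$a_dsc, dsc_amplitude(p0), tolerance = 0.05)
  expect_equal(fit0$tau_dsc, 60e-6, tolerance = 0.05)
  expect_lt(fit0$tau_fast, 1e-3)
  # with the reference set's bleach channels open the transient amplitude
  # is shaved slightly; extraction stays within 10% of the closed form
  tr <- simulate_trace(ref, wf, sampling = 5e-6, method = "reduced")
  fit <- fit_dsc(tr, tau_gsr = 1 / ref$k_gsr, k_ex = ref$k_ex, k_f = ref$k_f)
  expect_equal(fit$a_dsc, dsc_amplitude(ref), tolerance = 0.10)
  expect_equal(fit$tau_dsc, 60e-6, tolerance = 0.15)
})

test_that("a trace without dark-state conversion is flagged", {
  p <- kinetic_params(k_ex = 1e7, k_f = 5.8e8, k_dsc = 0, k_gsr = 1e3,
                      k_SB = 50)
  wf <- make_waveform("constant", 5, duration = 10e-3)
  tr <- simulate_trace(p, wf, sampling = 5e-6, method = "reduced")
  fit <- suppressWarnings(fit_dsc(tr, tau_gsr = 1e-3, k_ex = p$k_ex,
                                  k_f = p$k_f))
  expect_true("no-dsc" %in% fit$flags)
  expect_lt(fit$a_dsc, 0.01)
})

test_that("mCherry-d-like traces show stronger dark-state conversion", {
  rs <- reference_parameter_sets()
  wf <- make_waveform("constant", 5, duration = 10e-3)
  fits <- lapply(rs, function(set) {
    p <- set$params
    tr <- simulate_trace(p, wf, sampling = 5e-6, method = "reduced")
    fit_dsc(tr, tau_gsr = 1 / p$k_gsr, k_ex = p$k_ex, k_f = p$k_f)
  })
  expect_gt(fits$mcherry_d_like$a_dsc, fits$mcherry_like$a_dsc)
})
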