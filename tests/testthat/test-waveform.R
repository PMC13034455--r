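# illumination waveforms and their average intensities

test_that("constant waveform is flat at the requested intensity", {
  wf <- make_waveform("constant", intensity_peak = 5, duration = 1e-3)
  expect_equal(wf$intensity(c(0, 5e-4, 1e-3)), c(5, 5, 5))
  expect_equal(average_intensity(wf), 5)
})

test_that("rectangular pulse pair switches at the documented edges", {
  wf <- make_waveform("rect_pulse_pair", intensity_peak = 10,
                      duration = 5e-3, pulse_width = 2e-3, dark_time = 1e-3)
  expect_equal(wf$intensity(c(0, 1e-3, 2e-3)), c(10, 10, 10))
  expect_equal(wf$intensity(c(2.1e-3, 2.9e-3)), c(0, 0))
  expect_equal(wf$intensity(c(3e-3, 4e-3, 5e-3)), c(10, 10, 10))
  expect_equal(average_intensity(wf), 10 * 4 / 5)
  expect_error(make_waveform("rect_pulse_pair", 10, duration = 5e-3,
                             dark_time = -1e-3), "dark_time")
  expect_error(make_waveform("constant", 5, duration = -1), "duration")
})

test_that("gaussian train average matches the closed-form pulse integral", {
  wf <- make_waveform("gaussian_train", intensity_peak = 5,
                      duration = 6.5e-3, pulse_width = 0.2e-3,
                      period = 0.65e-3)
  closed <- 5 * 0.2e-3 * sqrt(pi / (4 * log(2))) / 0.65e-3
  expect_equal(average_intensity(wf), closed, tolerance = 1e-3)
  expect_equal(length(wf$centers), 10)
  expect_lt(wf$truncation_fraction, 0.005)
  # intensity is zero in the inter-pulse gaps (beyond +/- 3 sigma)
  expect_equal(wf$intensity(wf$centers[1] + 4 * wf$sigma), 0)
})

test_that("matched-average peak inversion round-trips", {
  peak <- gaussian_peak_for_average(5, fwhm = 0.2e-3, period = 0.65e-3)
  wf <- make_waveform("gaussian_train", intensity_peak = peak,
                      duration = 65e-3, pulse_width = 0.2e-3,
                      period = 0.65e-3)
  expect_equal(average_intensity(wf), 5, tolerance = 2e-3)
})

test_that("the interpulse delay can be read as period or as gap", {
  wf_p <- make_waveform("gaussian_train", 5, duration = 10e-3,
                        period = 0.65e-3, delay_as = "period")
  wf_g <- make_waveform("gaussian_train", 5, duration = 10e-3,
                        period = 0.65e-3, delay_as = "gap")
  expect_equal(wf_p$period, 0.65e-3)
  expect_equal(wf_g$period, 0.65e-3 + 6 * wf_g$sigma)
})
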