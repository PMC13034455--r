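# multi-exponential fitting and the weighted-average time constant

test_that("a noise-free biexponential is recovered to machine accuracy", {
  t <- seq(0, 0.5, length.out = 1000)
  y <- 0.6 * exp(-t / 0.01) + 0.4 * exp(-t / 0.1)
  fit <- fit_multiexponential(tibble::tibble(time = t, signal = y), n = 2,
                              with_offset = FALSE)
  expect_equal(fit$amplitudes, c(0.6, 0.4), tolerance = 1e-6)
  expect_equal(fit$tau, c(0.01, 0.1), tolerance = 1e-6)
  expect_length(fit$flags, 0)
  # deterministic: same data, same result
  fit2 <- fit_multiexponential(tibble::tibble(time = t, signal = y), n = 2,
                               with_offset = FALSE)
  expect_identical(fit$tau, fit2$tau)
  # components come back fastest-first with CIs containing the estimates
  expect_true(all(diff(fit$tau) > 0))
  td <- tidy(fit)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
})

test_that("triexponential with offset is recovered on clean data", {
  t <- seq(0, 0.2, length.out = 2000)
  y <- 0.3 * exp(-t / 5e-4) + 0.4 * exp(-t / 8e-3) +
    0.2 * exp(-t / 6e-2) + 0.1
  fit <- fit_multiexponential(tibble::tibble(time = t, signal = y), n = 3,
                              with_offset = TRUE)
  expect_equal(fit$tau, c(5e-4, 8e-3, 6e-2), tolerance = 1e-4)
  expect_equal(fit$offset, 0.1, tolerance = 1e-4)
})

test_that("degenerate inputs are flagged, not hidden", {
  t <- seq(0, 0.1, length.out = 200)
  flat <- fit_multiexponential(tibble::tibble(time = t, signal = rep(2, 200)),
                               n = 1, with_offset = TRUE)
  expect_true("degenerate" %in% flat$flags)
  expect_equal(flat$amplitudes, 0)
  # single-exponential data fit with two components
  y <- exp(-t / 0.02)
  over <- fit_multiexponential(tibble::tibble(time = t, signal = y), n = 2,
                               with_offset = FALSE)
  expect_true(any(c("negligible-component", "overparameterized") %in%
                    over$flags))
  expect_error(
    fit_multiexponential(tibble::tibble(time = t[1:20], signal = y[1:20]),
                         n = 3, with_offset = TRUE),
    "at least 10")
})

test_that("weighted average time constant reproduces published arithmetic", {
  # published global-fit rows: amplitude-weighted means to the nearest ms
  expect_equal(round(weighted_avg_tau(67, 10, 33, 87)), 35)
  expect_equal(round(weighted_avg_tau(10, 63, 90, 5)), 11)
  expect_identical(weighted_avg_tau(25, 0.02, 25, 0.02), 0.02)
  expect_error(weighted_avg_tau(0, 1, 0, 2), "a1")
})
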