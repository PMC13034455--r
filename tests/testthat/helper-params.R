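# shared fixtures: kinetic parameter sets used across tests

# canonical mCherry-style example (q = 59)
example_params <- function(k_SB = 0, k_DB = 0) {
  kinetic_params(k_ex = 1e7, k_f = 5.8e8, k_dsc = 1.67e4, k_gsr = 1e3,
                 k_SB = k_SB, k_DB = k_DB)
}

# random parameter draw; regime = "paper" keeps the canonical separation of
# fast (bright-pool) and slow (dark/bleach) rates, "wide" stresses it
random_params <- function(regime = c("paper", "wide")) {
  regime <- match.arg(regime)
  if (regime == "paper") {
    kinetic_params(k_ex = 10^runif(1, 6, 7), k_f = 10^runif(1, 8, 9),
                   k_dsc = 10^runif(1, 3, log10(5e4)),
                   k_gsr = 10^runif(1, 3, log10(5e4)))
  } else {
    kinetic_params(k_ex = 10^runif(1, 6, 9), k_f = 10^runif(1, 6, 9),
                   k_dsc = 10^runif(1, 2, 5), k_gsr = 10^runif(1, 2, 5))
  }
}

# normalized ODE fluorescence decay under constant light, self-normalized at
# the first sample after bright-pool equilibration (as an experiment would)
ode_decay <- function(params, duration, n = 500, method = "full") {
  wf <- make_waveform("constant", 5, duration = duration)
  tr <- integrate_model(params, wf, sampling = duration / n, method = method)
  sig <- fluorescence_signal(tr)
  keep <- which(sig$time > 20 / (params$k_ex + params$k_f))
  tibble::tibble(time = sig$time[keep],
                 signal = sig$signal[keep] / sig$signal[keep[1]])
}
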