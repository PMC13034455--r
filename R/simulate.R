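#' Simulate a noisy fluorescence trace
#'
#' Integrates the three-state model over the given waveform and returns the
#' fluorescence proxy (excited-state population scaled by the bright-pool
#' ratio `q`, so the signal starts near 1 under constant illumination)
#' sampled on the requested grid, with optional seeded noise. Two calls with
#' the same seed produce identical traces.
#'
#' @param params A [kinetic_params()] object (`k_ex` at the waveform's
#'   reference intensity).
#' @param waveform A [make_waveform()] object.
#' @param sampling Time step (s) or vector of sample times.
#' @param noise A [noise_model()] or NULL.
#' @param method Integrator choice, see [integrate_model()].
#' @param spec Optional [fluorophore_spec()], recorded in the metadata.
#' @param ... Passed to [integrate_model()].
#'
#' @return A `pk_trace`: tibble with columns `time` (s) and `signal`
#'   (arbitrary units), with waveform, parameters, noise model and spec
#'   stored as attributes.
#' @export
simulate_trace <- function(params, waveform,
                           sampling = waveform$duration / 1000,
                           noise = NULL, method = "auto", spec = NULL, ...) {
  traj <- integrate_model(params, waveform, sampling = sampling,
                          method = method, ...)
  sig <- fluorescence_signal(traj)
  ref <- mean(head(sort(sig$signal, decreasing = TRUE), 3))
  sig$signal <- apply_noise(sig$signal, noise, ref = ref)
  new_trace(sig, waveform = waveform, params = params, noise = noise,
            spec = spec, method = attr(traj, "method"))
}

new_trace <- function(df, ...) {
  meta <- list(...)
  structure(as_tibble(df), class = c("pk_trace", class(as_tibble(df))),
            meta = meta)
}

#' Normalize a trace to its initial level
#'
#' Divides the signal by the mean of the first `n` samples (the package's
#' normalization convention for fitting).
#'
#' @param trace A data frame with `time` and `signal` columns.
#' @param n Number of leading samples to average (default 3).
#' @return The trace with normalized `signal`.
#' @export
normalize_trace <- function(trace, n = 3) {
  ref <- mean(head(trace$signal, n))
  if (!is.finite(ref) || ref == 0) abort("cannot normalize: zero initial signal.")
  trace$signal <- trace$signal / ref
  trace
}

#' Simulate a ground-state recovery (pulse-pair) experiment
#'
#' For each dark time, runs the two-pulse protocol (default 2 ms pulses)
#' and reads out the fluorescence levels the analysis uses: `FL` (start of
#' pulse 1, before dark-state conversion), `FB` (end of pulse 1), and `FR`
#' (start of pulse 2, after recovery during the dark interval). Readouts
#' average `readout_n` consecutive samples against shot noise. Up to noise,
#' `FB <= FR <= FL`.
#'
#' Noise-free trajectories are computed once per dark time; technical
#' replicates differ only in the noise realization, seeded deterministically
#' from the noise model's seed.
#'
#' @param params A [kinetic_params()] object (`k_ex` at `intensity_ref`).
#' @param dark_times Vector of dark times, s.
#' @param intensity_kw_cm2 Pulse intensity, kW/cm^2; `k_ex` is scaled by
#'   `intensity_kw_cm2 / intensity_ref`.
#' @param intensity_ref Intensity at which `params$k_ex` applies, kW/cm^2
#'   (default: the pulse intensity, i.e. no rescaling).
#' @param pulse_width Pulse exposure time, s (default 2 ms).
#' @param sampling Sample spacing within pulses, s (default 5 us).
#' @param noise A [noise_model()] or NULL.
#' @param replicates Technical replicates per dark time (default 1).
#' @param readout_n Samples averaged per readout (default 3).
#' @param method Integrator choice (default reduced; the protocol spans up
#'   to hundreds of ms).
#' @return A tibble with columns `dark_time`, `replicate`, `FL`, `FB`, `FR`.
#' @export
simulate_gsr_experiment <- function(params, dark_times,
                                    intensity_kw_cm2 = 10,
                                    intensity_ref = intensity_kw_cm2,
                                    pulse_width = 2e-3, sampling = 5e-6,
                                    noise = NULL, replicates = 1,
                                    readout_n = 3, method = "reduced") {
  if (any(dark_times <= 0)) abort("`dark_times` must be positive.")
  params <- scale_kex(params, intensity_kw_cm2 / intensity_ref)
  base <- purrr::map(dark_times, function(td) {
    wf <- make_waveform("rect_pulse_pair", intensity_peak = intensity_kw_cm2,
                        duration = 2 * pulse_width + td,
                        pulse_width = pulse_width, dark_time = td)
    p2 <- pulse_width + td
    times <- sort(unique(c(seq(0, pulse_width, by = sampling),
                           seq(p2, p2 + pulse_width, by = sampling))))
    tr <- simulate_trace(params, wf, sampling = times, method = method)
    in_p1 <- tr$time <= pulse_width + 1e-15
    in_p2 <- tr$time >= p2 - 1e-15
    list(FL = head(tr$signal[in_p1], readout_n),
         FB = tail(tr$signal[in_p1], readout_n),
         FR = head(tr$signal[in_p2], readout_n))
  })
  grid <- tidyr::expand_grid(i = seq_along(dark_times),
                             replicate = seq_len(replicates))
  purrr::pmap_dfr(grid, function(i, replicate) {
    b <- base[[i]]
    vals <- c(b$FL, b$FB, b$FR)
    if (!is.null(noise) && noise$kind != "none") {
      vals <- apply_noise(vals, noise, ref = mean(b$FL),
                          seed = noise$seed + 1000L * i + replicate)
    }
    k <- length(b$FL)
    tibble(dark_time = dark_times[i], replicate = replicate,
           FL = mean(vals[seq_len(k)]),
           FB = mean(vals[k + seq_len(k)]),
           FR = mean(vals[2 * k + seq_len(k)]))
  })
}

#' Simulate an intensity series of photobleaching decays
#'
#' Generates normalized post-transient photobleaching traces at several
#' illumination intensities from the biexponential law used throughout the
#' analysis: a shared intrinsic term decaying at `k_SB` and an
#' intensity-dependent term decaying at the slow rate
#' \eqn{\lambda_{slow}(I)} of [slow_bleach_rate()] with `k_ex` scaled
#' linearly in intensity. The model itself does not constrain the
#' phenomenological amplitudes of the two terms; the default is an even
#' split (`a2 = 0.5`), which keeps both components identifiable in fits,
#' and collapses to a single intrinsic term (`a2 = 0`) when the dark bleach
#' pathway is closed. Pass `a2` to override per-intensity (e.g. with
#' published amplitude fractions).
#'
#' Traces are sampled on a log-spaced grid starting at `t_start` (the
#' sub-millisecond dark-state-conversion transient is excluded from
#' photobleaching analyses).
#'
#' @param params A [kinetic_params()] with `k_ex` at `intensity_ref`.
#' @param intensities Intensities to simulate, kW/cm^2.
#' @param intensity_ref Intensity at which `params$k_ex` applies, kW/cm^2.
#' @param t_start First sample time, s (default 1 ms).
#' @param duration Trace length, s; defaults per intensity to
#'   `3 / lambda_slow(I)` capped at 5 s.
#' @param n_points Samples per trace (default 400).
#' @param a2 Optional slow-term amplitude(s), recycled across intensities.
#' @param noise A [noise_model()] or NULL; seeds are offset per intensity.
#' @return A tibble with columns `intensity`, `time`, `signal`.
#' @export
simulate_bleach_family <- function(params, intensities, intensity_ref = 5,
                                   t_start = 1e-3, duration = NULL,
                                   n_points = 400, a2 = NULL, noise = NULL) {
  if (length(intensities) < 1) abort("need at least one intensity.")
  purrr::imap_dfr(as.list(intensities), function(int, idx) {
    p_i <- scale_kex(params, int / intensity_ref)
    lam <- slow_bleach_rate(p_i, warn_separation = FALSE)
    a2_i <- if (!is.null(a2)) {
      rep_len(a2, length(intensities))[idx]
    } else if (params$k_DB == 0 || params$k_dsc == 0 || params$k_gsr == 0) {
      0  # no dark bleach pathway: single intrinsic term
    } else {
      0.5
    }
    dur <- duration %||%
      min(max(3 / max(lam, 1e-6), 20 / max(params$k_SB, 1e-6)), 5)
    tt <- exp(seq(log(t_start), log(dur), length.out = n_points))
    sig <- (1 - a2_i) * exp(-params$k_SB * tt) + a2_i * exp(-lam * tt)
    if (!is.null(noise) && noise$kind != "none") {
      sig <- apply_noise(sig, noise, ref = 1, seed = noise$seed + 17L * idx)
    }
    tibble(intensity = int, time = tt, signal = sig)
  })
}
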