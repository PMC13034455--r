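#' Reference photophysical constants for mCherry and mCherry-d
#'
#' Published photophysical properties of mCherry and its dark-state-enhanced
#' variant mCherry-d: absorption/emission maxima, fluorescence lifetime,
#' extinction coefficient, quantum yield, and the measured dark-state
#' conversion and ground-state recovery time constants. Shipped as a
#' plain-text table in `inst/extdata`.
#'
#' @return A tibble with one row per fluorophore.
#' @export
reference_fluorophores <- function() {
  path <- system.file("extdata", "fluorophore_photophysics.csv",
                      package = "photokin", mustWork = TRUE)
  as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Reference global biexponential photobleaching fit parameters
#'
#' Published continuous-illumination photobleaching fit parameters for
#' mCherry and mCherry-d at 1, 5 and 10 kW/cm^2: amplitudes (percent),
#' shared time constant `tau1`, intensity-specific `tau2`, and the
#' amplitude-weighted average `tau_avg` (all ms). Used to verify the
#' weighted-average arithmetic and the printed fold-ratios.
#'
#' @return A tibble with columns `sample`, `intensity_kw_cm2`, `a1_pct`,
#'   `tau1_ms`, `a2_pct`, `tau2_ms`, `tau_avg_ms`.
#' @export
reference_bleach_fits <- function() {
  path <- system.file("extdata", "bleach_fit_params.csv",
                      package = "photokin", mustWork = TRUE)
  as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Emulation parameter sets for mCherry-like and mCherry-d-like kinetics
#'
#' Self-consistent kinetic parameter sets that emulate the measured
#' photophysics of mCherry and mCherry-d: `k_f` from the fluorescence
#' lifetime, `k_ex` from the extinction coefficient at the requested
#' intensity and wavelength, `k_dsc` and `k_gsr` from the measured time
#' constants, and bleach rates chosen so that the intrinsic S1-channel time
#' constant `1/k_SB` matches the published shared bleaching constant
#' (10 ms for mCherry, 63 ms for mCherry-d) while the dark channel carries
#' most of the bleach flux yet remains small against `k_gsr` (so the
#' pulse-pair recovery protocol stays a faithful `tau_gsr` probe). These
#' are emulation values, not measurements.
#'
#' The tabulated peak extinction coefficients are used even though typical
#' experiments excite off-peak (561/532 nm), so the absolute `k_ex` is an
#' approximation; q-dependent quantities inherit that caveat.
#'
#' @param intensity_kw_cm2 Illumination intensity, kW/cm^2 (default 5).
#' @param wavelength_nm Excitation wavelength, nm (default 561).
#' @return Named list (`mcherry_like`, `mcherry_d_like`) of lists with
#'   elements `spec` ([fluorophore_spec()]), `params` ([kinetic_params()]),
#'   `intensity_kw_cm2` and `wavelength_nm`.
#' @export
reference_parameter_sets <- function(intensity_kw_cm2 = 5,
                                     wavelength_nm = 561) {
  fl <- reference_fluorophores()
  mk <- function(row, k_SB, k_DB) {
    spec <- fluorophore_spec(row$name, row$lambda_abs_nm, row$lambda_ems_nm,
                             tau_fl = row$tau_fl_ns, epsilon = row$epsilon,
                             phi = row$phi, tau_dsc = row$tau_dsc_us,
                             tau_gsr = row$tau_gsr_ms)
    list(spec = spec,
         params = kinetic_params_from_spec(spec, intensity_kw_cm2,
                                           wavelength_nm, k_SB = k_SB,
                                           k_DB = k_DB),
         intensity_kw_cm2 = intensity_kw_cm2,
         wavelength_nm = wavelength_nm)
  }
  list(
    mcherry_like   = mk(fl[fl$name == "mCherry", ],   k_SB = 1 / 10e-3,
                        k_DB = 30),
    mcherry_d_like = mk(fl[fl$name == "mCherry-d", ], k_SB = 1 / 63e-3,
                        k_DB = 20)
  )
}
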