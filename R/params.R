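#' Kinetic parameters of the three-state photophysical model
#'
#' Bundles the six rate constants of the ground/excited/dark model with
#' irreversible photobleaching: excitation (`k_ex`), return to the ground
#' state (`k_f`, taken as the total S1 depopulation rate, i.e. the reciprocal
#' of the fluorescence lifetime), dark-state conversion (`k_dsc`),
#' ground-state recovery (`k_gsr`), and photobleaching from the bright and
#' dark states (`k_SB`, `k_DB`). All rates are in s^-1.
#'
#' The dimensionless ratios `q = k_f/k_ex + 1`, `q' = k_f/k_ex` and
#' `q_D = k_dsc/k_gsr` govern the equilibrium bright-pool fractions and the
#' dark-state occupancy; they are available via [q_ratio()], [q_prime()] and
#' [q_dark()].
#'
#' @param k_ex Excitation rate S0 -> S1, s^-1. In time-varying illumination
#'   this is the rate at the waveform's reference (peak) intensity.
#' @param k_f S1 -> S0 return rate, s^-1 (1/fluorescence lifetime).
#' @param k_dsc Dark-state conversion rate constant S1 -> D, s^-1.
#' @param k_gsr Ground-state recovery rate constant D -> S0, s^-1.
#' @param k_SB Photobleaching rate from S1, s^-1.
#' @param k_DB Photobleaching rate from the dark state, s^-1.
#'
#' @return An object of class `pk_params` (a named list of the six rates).
#' @examples
#' kinetic_params(k_ex = 1e7, k_f = 5.8e8, k_dsc = 1.67e4, k_gsr = 1e3)
#' @export
kinetic_params <- function(k_ex, k_f, k_dsc = 0, k_gsr = 0,
                           k_SB = 0, k_DB = 0) {
  rates <- list(k_ex = k_ex, k_f = k_f, k_dsc = k_dsc, k_gsr = k_gsr,
                k_SB = k_SB, k_DB = k_DB)
  for (nm in names(rates)) {
    v <- rates[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      abort(sprintf("`%s` must be a single non-negative number.", nm))
    }
  }
  structure(rates, class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("<three-state kinetic parameters (s^-1)>\n")
  cat(sprintf("  k_ex  = %.4g   k_f   = %.4g\n", x$k_ex, x$k_f))
  cat(sprintf("  k_dsc = %.4g   k_gsr = %.4g\n", x$k_dsc, x$k_gsr))
  cat(sprintf("  k_SB  = %.4g   k_DB  = %.4g\n", x$k_SB, x$k_DB))
  if (x$k_ex > 0 && x$k_f > 0) {
    cat(sprintf("  q = %.4g", q_ratio(x)))
    if (x$k_gsr > 0) cat(sprintf("   q_D = %.4g", q_dark(x)))
    cat("\n")
  }
  invisible(x)
}

#' Dimensionless ratios of the three-state model
#'
#' `q_ratio()` returns \eqn{q = k_f/k_{ex} + 1}, `q_prime()` returns
#' \eqn{q' = k_f/k_{ex}} (so `q = q' + 1` exactly), and `q_dark()` returns
#' \eqn{q_D = k_{dsc}/k_{gsr}}. `1/q` is the equilibrium fraction of the
#' bright pool residing in S1.
#'
#' @param params A [kinetic_params()] object.
#' @return A single number.
#' @export
q_ratio <- function(params) q_prime(params) + 1

#' @rdname q_ratio
#' @export
q_prime <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  if (params$k_ex <= 0 || params$k_f <= 0) {
    abort("q and q' require k_ex > 0 and k_f > 0.")
  }
  params$k_f / params$k_ex
}

#' @rdname q_ratio
#' @export
q_dark <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  if (params$k_gsr <= 0) abort("q_D requires k_gsr > 0.")
  params$k_dsc / params$k_gsr
}

#' Measurable photophysics of a fluorophore
#'
#' Holds the spectroscopic quantities from which the model's fast rates
#' derive: `k_f = 1/tau_fl` and `k_ex` via [excitation_rate()] from the
#' extinction coefficient. Peak-wavelength extinction coefficients are
#' commonly tabulated; when exciting off-peak the effective epsilon at the
#' laser line should be used if known.
#'
#' @param name Label for the fluorophore.
#' @param lambda_abs,lambda_ems Absorption and emission maxima, nm.
#' @param tau_fl Fluorescence lifetime, ns.
#' @param epsilon Extinction coefficient, M^-1 cm^-1.
#' @param phi Fluorescence quantum yield in (0, 1].
#' @param tau_dsc Optional known dark-state conversion time constant, us.
#' @param tau_gsr Optional known ground-state recovery time constant, ms.
#'
#' @return An object of class `pk_fluorophore`.
#' @examples
#' fluorophore_spec("mCherry", 587, 610, tau_fl = 1.72, epsilon = 74000,
#'                  phi = 0.25, tau_dsc = 60, tau_gsr = 1.0)
#' @export
fluorophore_spec <- function(name, lambda_abs, lambda_ems, tau_fl, epsilon,
                             phi, tau_dsc = NA_real_, tau_gsr = NA_real_) {
  if (tau_fl <= 0) abort("`tau_fl` must be > 0 (ns).")
  if (epsilon <= 0) abort("`epsilon` must be > 0.")
  if (phi <= 0 || phi > 1) abort("`phi` must be in (0, 1].")
  structure(list(name = name, lambda_abs = lambda_abs,
                 lambda_ems = lambda_ems, tau_fl = tau_fl,
                 epsilon = epsilon, phi = phi,
                 tau_dsc = tau_dsc, tau_gsr = tau_gsr),
            class = "pk_fluorophore")
}

#' @export
print.pk_fluorophore <- function(x, ...) {
  cat(sprintf("<fluorophore: %s>\n", x$name))
  cat(sprintf("  abs/ems %g/%g nm, tau_fl %g ns, eps %g, phi %g\n",
              x$lambda_abs, x$lambda_ems, x$tau_fl, x$epsilon, x$phi))
  if (!is.na(x$tau_dsc)) cat(sprintf("  tau_dsc %g us", x$tau_dsc))
  if (!is.na(x$tau_gsr)) cat(sprintf("  tau_gsr %g ms", x$tau_gsr))
  if (!is.na(x$tau_dsc) || !is.na(x$tau_gsr)) cat("\n")
  invisible(x)
}

#' Build kinetic parameters from measurable photophysics
#'
#' Derives `k_f = 1/tau_fl`, `k_ex` from the illumination intensity and
#' extinction coefficient, and `k_dsc`/`k_gsr` from the spec's known time
#' constants when present.
#'
#' @param spec A [fluorophore_spec()].
#' @param intensity_kw_cm2 Illumination intensity at the sample, kW/cm^2.
#' @param wavelength_nm Excitation wavelength, nm. Defaults to the absorption
#'   maximum.
#' @param k_SB,k_DB Photobleaching rate constants, s^-1.
#' @return A [kinetic_params()] object.
#' @export
kinetic_params_from_spec <- function(spec, intensity_kw_cm2,
                                     wavelength_nm = spec$lambda_abs,
                                     k_SB = 0, k_DB = 0) {
  stopifnot(inherits(spec, "pk_fluorophore"))
  kinetic_params(
    k_ex  = excitation_rate(intensity_kw_cm2 * 1000, wavelength_nm,
                            spec$epsilon),
    k_f   = 1 / (spec$tau_fl * 1e-9),
    k_dsc = if (is.na(spec$tau_dsc)) 0 else 1 / (spec$tau_dsc * 1e-6),
    k_gsr = if (is.na(spec$tau_gsr)) 0 else 1 / (spec$tau_gsr * 1e-3),
    k_SB = k_SB, k_DB = k_DB
  )
}

# internal: copy of params with k_ex rescaled by an intensity ratio
scale_kex <- function(params, factor) {
  p <- unclass(params)
  p$k_ex <- p$k_ex * factor
  structure(p, class = "pk_params")
}

#' Equilibrium bright-pool fractions
#'
#' Fractions of the bright pool (S0 + S1) in each state under the rapid
#' S0/S1 equilibrium `k_f [S1] = k_ex [S0]`: the S1 fraction is `1/q`.
#'
#' @param params A [kinetic_params()] object with `k_ex > 0`, `k_f > 0`.
#' @return Named numeric vector `c(S0 = ..., S1 = ...)` summing to 1.
#' @examples
#' equilibrium_fractions(kinetic_params(k_ex = 1e7, k_f = 5.8e8))
#' @export
equilibrium_fractions <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  if (params$k_ex <= 0 && params$k_f <= 0) {
    abort("k_ex and k_f cannot both be zero.")
  }
  s1 <- params$k_ex / (params$k_ex + params$k_f)
  c(S0 = 1 - s1, S1 = s1)
}
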