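#' Closed-form sub-millisecond fluorescence decay
#'
#' Under the rapid S0/S1 equilibrium and with photobleaching negligible over
#' short (<1 ms) windows, the normalized excited-state population decays as
#' a single exponential from 1 to a plateau:
#' \deqn{S_{1,norm}(t) = a_{dsc} e^{-(k_{gsr} + k_{dsc}/q)t} + (1 - a_{dsc})}
#' with the dark-state conversion amplitude \eqn{a_{dsc}} given by
#' [dsc_amplitude()] and \eqn{q = k_f/k_{ex} + 1}.
#'
#' @param t Time(s) since illumination onset, s.
#' @param params A [kinetic_params()] object (bleach rates are ignored; the
#'   expression assumes `k_SB = k_DB = 0`).
#' @return Normalized signal, 1 at `t = 0`, monotone non-increasing.
#' @export
s1_norm_analytic <- function(t, params) {
  a <- dsc_amplitude(params)
  rate <- dsc_observed_rate(params)
  a * exp(-rate * t) + (1 - a)
}

#' Observed sub-millisecond relaxation rate
#'
#' The exponent of the fast decay, \eqn{k_{gsr} + k_{dsc}/q}. Reported for
#' diagnostics; the amplitude is the preferred observable for extracting
#' `tau_dsc` because the exponent is highly sensitive to the few earliest
#' samples of a trace.
#'
#' @inheritParams s1_norm_analytic
#' @return Rate in s^-1 (always >= `k_gsr`).
#' @export
dsc_observed_rate <- function(params) {
  params$k_gsr + params$k_dsc / q_ratio(params)
}

#' Dark-state conversion amplitude
#'
#' The fractional fluorescence drop of the fast decay,
#' \deqn{a_{dsc} = k_{dsc} / (k_{dsc} + q\,k_{gsr}),}
#' strictly increasing in `k_dsc` and in `k_ex` (through `q`), strictly
#' decreasing in `k_gsr`. When `k_gsr = 0` and `k_dsc > 0` the limit 1 is
#' returned (all population eventually trapped in the dark state).
#'
#' @inheritParams s1_norm_analytic
#' @return Amplitude in `[0, 1]`.
#' @examples
#' dsc_amplitude(kinetic_params(k_ex = 1e7, k_f = 8e7, k_dsc = 1e4,
#'                              k_gsr = 1e3))  # q = 9 -> ~0.526
#' @export
dsc_amplitude <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  if (params$k_dsc == 0) return(0)
  if (params$k_gsr == 0) return(1)
  q <- q_ratio(params)
  params$k_dsc / (params$k_dsc + q * params$k_gsr)
}

#' Fast-decay prediction (amplitude, rate, plateau)
#'
#' @inheritParams s1_norm_analytic
#' @return A one-row tibble with `a_dsc`, `rate_fast` (s^-1) and `plateau`
#'   (`a_dsc + plateau = 1` exactly).
#' @export
dsc_prediction <- function(params) {
  a <- dsc_amplitude(params)
  tibble(a_dsc = a, rate_fast = dsc_observed_rate(params), plateau = 1 - a)
}

#' Dark-state conversion time constant from the measured amplitude
#'
#' Inverts the amplitude expression: given a fitted `a_dsc` and
#' independently measured `tau_gsr`, `k_ex` and `k_f`,
#' \deqn{k_{dsc} = a_{dsc}\, q\, k_{gsr} / (1 - a_{dsc}), \quad
#'       \tau_{dsc} = 1/k_{dsc}.}
#' This is the default extraction route for `tau_dsc`; the fitted fast
#' exponent is reported only as a diagnostic.
#'
#' @param a_dsc Measured dark-state conversion amplitude, in (0, 1).
#' @param tau_gsr Ground-state recovery time constant, s.
#' @param k_ex,k_f Excitation and S1-return rates, s^-1.
#' @return `tau_dsc` in seconds.
#' @export
tau_dsc_from_amplitude <- function(a_dsc, tau_gsr, k_ex, k_f) {
  if (any(a_dsc <= 0) || any(a_dsc >= 1)) {
    abort("`a_dsc` must lie strictly in (0, 1).")
  }
  if (any(tau_gsr <= 0) || any(k_ex <= 0) || any(k_f <= 0)) {
    abort("`tau_gsr`, `k_ex` and `k_f` must be > 0.")
  }
  q <- k_f / k_ex + 1
  k_dsc <- a_dsc * q * (1 / tau_gsr) / (1 - a_dsc)
  1 / k_dsc
}

# reduced two-pool rate matrix: bright pool N = S0 + S1 and dark pool D
reduced_matrix <- function(params) {
  q <- q_ratio(params)
  matrix(c(-(params$k_dsc + params$k_SB) / q, params$k_gsr,
           params$k_dsc / q, -(params$k_gsr + params$k_DB)),
         nrow = 2, byrow = TRUE)
}

#' Slow photobleaching rate of the reduced two-pool system
#'
#' The long-time fluorescence decay rate: the slow eigenvalue magnitude of
#' \deqn{dN/dt = -(k_{dsc}+k_{SB})N/q + k_{gsr}D, \quad
#'       dD/dt = (k_{dsc}/q)N - (k_{gsr}+k_{DB})D.}
#' In the strong-separation limit this approaches
#' \eqn{(k_{SB} + k_{DB} q_D)/(q + q_D)}; with `k_dsc = 0` it reduces to
#' `k_SB/q`, and as \eqn{q_D \to \infty} it tends to `k_DB`. It increases
#' with `k_ex` (through `q`), which is why higher illumination intensity
#' accelerates dark-state-mediated photobleaching.
#'
#' A warning is issued when the fast/slow eigenvalue separation is below
#' 10x, where a single "slow rate" stops being a meaningful summary.
#'
#' @inheritParams s1_norm_analytic
#' @param warn_separation Emit the timescale-separation warning
#'   (default TRUE).
#' @return Slow rate \eqn{\lambda_{slow}} in s^-1.
#' @export
slow_bleach_rate <- function(params, warn_separation = TRUE) {
  stopifnot(inherits(params, "pk_params"))
  m <- reduced_matrix(params)
  tr <- m[1, 1] + m[2, 2]
  dt <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (dt <= 0) return(0)  # no open bleach channel
  disc <- sqrt(max(tr^2 - 4 * dt, 0))
  lam_slow <- 2 * dt / (abs(tr) + disc)   # stable form of the small root
  lam_fast <- (abs(tr) + disc) / 2
  if (warn_separation && lam_slow > 0 && lam_fast / lam_slow < 10) {
    warn(sprintf(
      "fast/slow rate separation is only %.1fx; the slow-rate summary is marginal.",
      lam_fast / lam_slow))
  }
  lam_slow
}

#' Biexponential photobleaching prediction
#'
#' Summarizes the model's photobleaching decay in the convention of the
#' global fitting stage: an intrinsic S1-channel rate `rate_S1 = k_SB`
#' (whose reciprocal is the shared time constant of global fits) and the
#' intensity-dependent slow rate `rate_dark` from [slow_bleach_rate()],
#' together with the eigenmode amplitudes `a1` (fast mode) and `a2` (slow
#' mode) obtained by projecting the initial all-bright condition onto the
#' eigenvectors of the reduced two-pool system (`a1 + a2 = 1`).
#'
#' @inheritParams s1_norm_analytic
#' @return A one-row tibble: `rate_S1`, `rate_dark`, `rate_fast` (fast
#'   eigenvalue, diagnostics), `a1`, `a2`.
#' @export
bleach_prediction <- function(params) {
  eig <- reduced_eigen(params)
  tibble(rate_S1 = params$k_SB,
         rate_dark = eig$lam_slow,
         rate_fast = eig$lam_fast,
         a1 = eig$a_fast, a2 = eig$a_slow)
}

# eigen decomposition of the reduced system with initial (N, D) = (1, 0);
# returns rates (magnitudes) and the bright-pool projections a_fast + a_slow = 1
reduced_eigen <- function(params) {
  m <- reduced_matrix(params)
  e <- eigen(m)
  ord <- order(abs(e$values))           # slow first
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  coefs <- tryCatch(solve(vecs, c(1, 0)), error = function(err) NULL)
  if (is.null(coefs)) {
    # degenerate eigenvectors (e.g. fully decoupled dark pool): all weight
    # stays in the bright-pool mode
    return(list(lam_slow = abs(vals[1]), lam_fast = abs(vals[2]),
                a_slow = 1, a_fast = 0))
  }
  a <- Re(coefs * vecs[1, ])            # contribution of each mode to N(t)
  list(lam_slow = abs(Re(vals[1])), lam_fast = abs(Re(vals[2])),
       a_slow = a[1], a_fast = a[2])
}

#' Closed-form photobleaching decay
#'
#' The exact bright-pool solution of the reduced two-pool system,
#' \deqn{N(t) = a_1 e^{-\lambda_{fast} t} + a_2 e^{-\lambda_{slow} t},}
#' with eigenvalues and projections from [bleach_prediction()]. This matches
#' the full stiff-ODE fluorescence trace (normalized) everywhere beyond the
#' nanosecond bright-pool equilibration, including the dark-state-conversion
#' transient. With `envelope = TRUE` the same solution is divided by its
#' no-bleach counterpart, isolating the bleaching envelope: it is
#' identically 1 when `k_SB = k_DB = 0` and reduces to `exp(-k_SB t / q)`
#' when `k_dsc = 0`.
#'
#' @param t Time(s), s.
#' @inheritParams s1_norm_analytic
#' @param envelope Divide out the no-bleach solution (default FALSE).
#' @return Normalized signal, 1 at `t = 0`.
#' @export
bleach_decay_analytic <- function(t, params, envelope = FALSE) {
  eig <- reduced_eigen(params)
  out <- eig$a_fast * exp(-eig$lam_fast * t) +
    eig$a_slow * exp(-eig$lam_slow * t)
  if (envelope) {
    p0 <- unclass(params)
    p0$k_SB <- 0
    p0$k_DB <- 0
    e0 <- reduced_eigen(structure(p0, class = "pk_params"))
    ref <- e0$a_fast * exp(-e0$lam_fast * t) +
      e0$a_slow * exp(-e0$lam_slow * t)
    out <- out / ref
  }
  out
}
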