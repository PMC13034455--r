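#' Detector noise models for synthetic traces
#'
#' Describes the noise applied to a noise-free fluorescence signal. All
#' models preserve the expectation of the signal:
#' * `"poisson"`: shot noise; the signal is converted to expected photon
#'   counts via `photons_per_unit_signal`, Poisson-sampled, and converted
#'   back.
#' * `"gaussian"`: additive detector noise with standard deviation
#'   `gaussian_sd` expressed as a fraction of the initial (maximum early)
#'   signal; a per-point signal-to-noise ratio of 100 corresponds to
#'   `gaussian_sd = 0.01`.
#' * `"poisson+gaussian"`: both, shot noise first.
#' * `"none"`: pass-through.
#'
#' @param kind One of `"none"`, `"poisson"`, `"gaussian"`,
#'   `"poisson+gaussian"`.
#' @param photons_per_unit_signal Expected photon counts per unit of signal.
#' @param gaussian_sd Additive noise SD as a fraction of the initial signal.
#' @param seed Integer seed; mandatory for any kind other than `"none"`.
#' @return An object of class `pk_noise`.
#' @export
noise_model <- function(kind = c("none", "poisson", "gaussian",
                                 "poisson+gaussian"),
                        photons_per_unit_signal = 1e6,
                        gaussian_sd = 0.01, seed = NULL) {
  kind <- match.arg(kind)
  if (kind != "none" && is.null(seed)) {
    abort("a `seed` is mandatory when noise is applied.")
  }
  structure(list(kind = kind,
                 photons_per_unit_signal = photons_per_unit_signal,
                 gaussian_sd = gaussian_sd, seed = seed),
            class = "pk_noise")
}

#' Apply a noise model to a signal
#'
#' @param signal Numeric vector of noise-free signal values.
#' @param noise A [noise_model()] (or NULL for no noise).
#' @param ref Reference signal level against which `gaussian_sd` is scaled;
#'   defaults to the mean of the three largest early values.
#' @param seed Override for the model's seed (used to decorrelate
#'   replicates deterministically).
#' @return Noisy signal vector, identical for identical seeds.
#' @export
apply_noise <- function(signal, noise, ref = NULL, seed = noise$seed) {
  if (is.null(noise) || noise$kind == "none") return(signal)
  stopifnot(inherits(noise, "pk_noise"))
  ref <- ref %||% mean(head(sort(signal, decreasing = TRUE), 3))
  withr::with_seed(as.integer(seed), {
    out <- signal
    if (noise$kind %in% c("poisson", "poisson+gaussian")) {
      ppu <- noise$photons_per_unit_signal
      out <- rpois(length(out), pmax(out, 0) * ppu) / ppu
    }
    if (noise$kind %in% c("gaussian", "poisson+gaussian")) {
      out <- out + rnorm(length(out), 0, noise$gaussian_sd * ref)
    }
    out
  })
}
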