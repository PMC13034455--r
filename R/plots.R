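#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's objects:
#' population trajectories (all four states on a log time axis),
#' fluorescence traces, ground-state recovery curves with their exponential
#' fit, global photobleaching fits (data plus fitted curves per intensity),
#' and pulsed-versus-continuous comparisons (traces with the connected peak
#' decay).
#'
#' @param object The object to plot.
#' @param log_time Use a log10 time axis where sensible (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @name photokin-autoplot
NULL

#' @rdname photokin-autoplot
#' @export
autoplot.pk_trajectory <- function(object, log_time = TRUE, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("S0", "S1", "D", "B"),
                            names_to = "state", values_to = "population")
  p <- ggplot(df[df$time > 0 | !log_time, ],
              aes(.data$time, .data$population, colour = .data$state)) +
    geom_line() +
    labs(x = "time (s)", y = "population fraction", colour = NULL)
  if (log_time) p <- p + scale_x_log10()
  p
}

#' @rdname photokin-autoplot
#' @export
autoplot.pk_trace <- function(object, log_time = TRUE, ...) {
  p <- ggplot(as_tibble(object)[object$time > 0 | !log_time, ],
              aes(.data$time, .data$signal)) +
    geom_line(colour = "grey30") +
    labs(x = "time (s)", y = "fluorescence (a.u.)")
  if (log_time) p <- p + scale_x_log10()
  p
}

#' @rdname photokin-autoplot
#' @export
autoplot.pk_recovery_fit <- function(object, ...) {
  curve <- tibble(
    dark_time = 10^seq(log10(min(object$points$dark_time)),
                       log10(max(object$points$dark_time)),
                       length.out = 200))
  curve$PR <- object$p_max * (1 - exp(-curve$dark_time / object$tau_gsr))
  ggplot(object$points, aes(.data$dark_time, .data$PR)) +
    geom_point() +
    geom_line(data = curve, colour = "firebrick") +
    scale_x_log10() +
    labs(x = "dark time (s)", y = "percent recovery",
         subtitle = sprintf("tau_gsr = %.3g ms", object$tau_gsr * 1e3))
}

#' @rdname photokin-autoplot
#' @export
autoplot.pk_global_fit <- function(object, ...) {
  bi <- object$by_intensity
  t_grid <- 10^seq(log10(object$t_start),
                   log10(object$t_start * 3000), length.out = 300)
  fits <- purrr::map_dfr(seq_len(nrow(bi)), function(i) {
    tibble(intensity = bi$intensity[i], time = t_grid,
           signal = bi$a1[i] * exp(-t_grid / object$tau1) +
             bi$a2[i] * exp(-t_grid / bi$tau2[i]) + bi$b[i])
  })
  ggplot(fits, aes(.data$time, .data$signal,
                   colour = factor(.data$intensity))) +
    geom_line() +
    scale_x_log10() +
    labs(x = "time (s)", y = "normalized fluorescence",
         colour = expression("intensity (kW/cm"^2 * ")"),
         subtitle = sprintf("shared tau1 = %.3g ms", object$tau1 * 1e3))
}

#' @rdname photokin-autoplot
#' @export
autoplot.pk_illum_comparison <- function(object, ...) {
  tr <- bind_rows(
    mutate(as_tibble(object$traces$continuous), mode = "continuous"),
    mutate(as_tibble(object$traces$pulsed), mode = "pulsed"))
  peaks <- mutate(object$traces$peaks, mode = "pulsed")
  ggplot(tr[tr$time > 0, ],
         aes(.data$time, .data$signal, colour = .data$mode)) +
    geom_line(alpha = 0.5) +
    geom_line(data = peaks[peaks$time > 0, ], linewidth = 0.8) +
    scale_x_log10() +
    labs(x = "time (s)", y = "fluorescence (a.u.)", colour = NULL,
         subtitle = sprintf("enhancement factor %.2f", object$enhancement))
}
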