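#' Fit a multi-exponential decay
#'
#' Nonlinear least-squares fit of
#' \eqn{y(t) = \sum_i a_i e^{-t/\tau_i} (+ b)} with `n` in 1..3. Robustness
#' against the notorious multi-exponential local minima comes from a
#' multi-start strategy: candidate time constants are placed on a log grid
#' spanning the fit window (half-decade spacing), amplitudes and offset are
#' profiled out by linear least squares for every candidate combination
#' (variable projection), and the best-ranked candidates are refined with
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]). The lowest residual wins;
#' ties are broken by the smallest fast time constant. The procedure is
#' deterministic: fixed data and grid give identical results.
#'
#' Components are reported sorted fastest-first. 95% confidence intervals
#' come from the linearized fit covariance. Degenerate situations are
#' flagged rather than hidden: a constant input yields a zero-amplitude
#' result flagged `"degenerate"`, a negligible component (relative to the
#' signal range) flags `"negligible-component"`, and near-duplicated time
#' constants flag `"overparameterized"`.
#'
#' @param trace Data frame with columns `time` (s) and `signal`.
#' @param n Number of exponential components (1, 2 or 3).
#' @param with_offset Include a constant offset `b` (default TRUE).
#' @param t_min,t_max Fit window, s (defaults: full trace).
#' @param n_refine How many ranked starts to polish with LM (default 4).
#' @param nonneg Constrain all amplitudes to be non-negative (appropriate
#'   for pure decays, where sign-flipped canceling component pairs are
#'   unphysical; default FALSE).
#'
#' @return A `pk_exp_fit` object; see [tidy.pk_exp_fit()] and
#'   [glance.pk_exp_fit()].
#' @examples
#' t <- seq(0, 0.5, length.out = 500)
#' y <- 0.6 * exp(-t / 0.01) + 0.4 * exp(-t / 0.1)
#' fit <- fit_multiexponential(data.frame(time = t, signal = y), n = 2,
#'                             with_offset = FALSE)
#' tidy(fit)
#' @export
fit_multiexponential <- function(trace, n = 2, with_offset = TRUE,
                                 t_min = NULL, t_max = NULL, n_refine = 4,
                                 nonneg = FALSE) {
  if (!n %in% 1:3) abort("`n` must be 1, 2 or 3.")
  df <- as_tibble(trace)[, c("time", "signal")]
  if (!is.null(t_min)) df <- df[df$time >= t_min, ]
  if (!is.null(t_max)) df <- df[df$time <= t_max, ]
  df <- df[is.finite(df$signal), ]
  n_par <- n * 2 + as.integer(with_offset)
  if (nrow(df) < 10 * n_par) {
    abort(sprintf("fit window holds %d points; need at least 10 per free parameter (%d).",
                  nrow(df), n_par))
  }
  t <- df$time - min(df$time)   # fit from window origin
  y <- df$signal
  rng <- diff(range(y))

  if (rng < 1e-12 * max(abs(y), 1)) {
    return(new_exp_fit(amp = rep(0, n), tau = rep(NA_real_, n),
                       b = mean(y), with_offset = with_offset,
                       ci = NULL, rss = 0, n_points = length(y),
                       flags = "degenerate", window = range(df$time),
                       data = df))
  }

  starts <- multiexp_starts(t, y, n, with_offset, nonneg)
  ranked <- starts[order(vapply(starts, `[[`, 0, "rss"))]
  best <- NULL
  for (s in head(ranked, n_refine)) {
    fit <- refine_multiexp(t, y, n, with_offset, s, nonneg)
    if (is.null(fit)) next
    if (is.null(best) || fit$rss < best$rss * (1 - 1e-10) ||
        (abs(fit$rss - best$rss) <= best$rss * 1e-10 &&
         min(fit$tau) < min(best$tau))) {
      best <- fit
    }
  }
  if (is.null(best)) {
    # LM refinement failed everywhere; fall back to best projected start
    s <- ranked[[1]]
    best <- list(amp = s$amp, tau = s$tau, b = s$b, rss = s$rss, vcov = NULL)
    flags <- "no-convergence"
  } else {
    flags <- character()
  }

  ord <- order(best$tau)
  amp <- best$amp[ord]; tau <- best$tau[ord]
  if (any(abs(amp) < 1e-3 * rng)) flags <- c(flags, "negligible-component")
  if (n > 1 && any(tau[-1] / tau[-n] < 1.05)) {
    flags <- c(flags, "overparameterized")
  }

  ci <- NULL
  if (!is.null(best$vcov)) {
    se <- sqrt(pmax(diag(best$vcov), 0))
    est <- c(best$amp, best$tau, if (with_offset) best$b)
    z <- qnorm(0.975)
    ci_all <- cbind(est - z * se, est + z * se)
    ci <- list(amp = ci_all[seq_len(n), , drop = FALSE][ord, , drop = FALSE],
               tau = ci_all[n + seq_len(n), , drop = FALSE][ord, , drop = FALSE],
               b = if (with_offset) ci_all[2 * n + 1, ])
  }
  new_exp_fit(amp = amp, tau = tau, b = if (with_offset) best$b else 0,
              with_offset = with_offset, ci = ci, rss = best$rss,
              n_points = length(y), flags = flags, window = range(df$time),
              data = df)
}

# variable-projection starts: grid over tau combinations, linear solve for
# amplitudes (+ offset)
multiexp_starts <- function(t, y, n, with_offset, nonneg = FALSE) {
  span <- diff(range(t))
  tau_lo <- max(min(diff(sort(unique(t)))), span / 1e5)
  grid <- 10^seq(log10(tau_lo), log10(span * 2), by = 0.5)
  combos <- utils::combn(seq_along(grid), n, simplify = FALSE)
  if (length(combos) > 200) {
    grid <- 10^seq(log10(tau_lo), log10(span * 2), by = 1)
    combos <- utils::combn(seq_along(grid), n, simplify = FALSE)
  }
  purrr::map(combos, function(idx) {
    tau <- grid[idx]
    X <- vapply(tau, function(tt) exp(-t / tt), numeric(length(t)))
    if (with_offset) X <- cbind(X, 1)
    fit <- lm.fit(X, y)
    amp <- fit$coefficients[seq_len(n)]
    amp[is.na(amp)] <- 0
    if (nonneg) amp <- pmax(amp, 0)
    b <- if (with_offset) fit$coefficients[n + 1] else 0
    if (is.na(b)) b <- 0
    rss <- if (nonneg) {
      pred <- X %*% c(amp, if (with_offset) b)
      sum((y - pred)^2)
    } else {
      sum(fit$residuals^2)
    }
    list(tau = tau, amp = unname(amp), b = unname(b), rss = rss)
  })
}

refine_multiexp <- function(t, y, n, with_offset, start, nonneg = FALSE) {
  pnames_a <- paste0("a", seq_len(n))
  pnames_tau <- paste0("tau", seq_len(n))
  start_list <- c(as.list(setNames(start$amp, pnames_a)),
                  as.list(setNames(start$tau, pnames_tau)),
                  if (with_offset) list(b = start$b))
  rhs <- paste(sprintf("%s * exp(-time / %s)", pnames_a, pnames_tau),
               collapse = " + ")
  if (with_offset) rhs <- paste(rhs, "+ b")
  fml <- stats::as.formula(paste("signal ~", rhs))
  lower <- c(rep(if (nonneg) 0 else -Inf, n),
             rep(min(diff(range(t))) * 1e-7, n),
             if (with_offset) -Inf)
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = data.frame(time = t, signal = y),
                      start = start_list, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  list(amp = unname(cf[pnames_a]), tau = unname(cf[pnames_tau]),
       b = if (with_offset) unname(cf[["b"]]) else 0,
       rss = sum(stats::resid(fit)^2), vcov = vc)
}

new_exp_fit <- function(amp, tau, b, with_offset, ci, rss, n_points, flags,
                        window, data) {
  structure(list(amplitudes = amp, tau = tau, offset = b,
                 with_offset = with_offset, ci = ci, rss = rss,
                 sigma = sqrt(rss / max(n_points - length(amp) * 2 -
                                          as.integer(with_offset), 1)),
                 n_components = length(amp), n_points = n_points,
                 flags = flags, window = window, data = data),
            class = "pk_exp_fit")
}

#' @export
print.pk_exp_fit <- function(x, ...) {
  cat(sprintf("<multi-exponential fit: %d component(s), %d points>\n",
              x$n_components, x$n_points))
  print(tidy(x))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a multi-exponential fit
#'
#' @param x A `pk_exp_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `conf.low`, `conf.high`, `units`.
#' @export
tidy.pk_exp_fit <- function(x, ...) {
  n <- x$n_components
  terms <- c(paste0("a", seq_len(n)), paste0("tau", seq_len(n)),
             if (x$with_offset) "b")
  est <- c(x$amplitudes, x$tau, if (x$with_offset) x$offset)
  lo <- hi <- rep(NA_real_, length(est))
  if (!is.null(x$ci)) {
    lo <- c(x$ci$amp[, 1], x$ci$tau[, 1], if (x$with_offset) x$ci$b[1])
    hi <- c(x$ci$amp[, 2], x$ci$tau[, 2], if (x$with_offset) x$ci$b[2])
  }
  tibble(term = terms, estimate = est, conf.low = lo, conf.high = hi,
         units = c(rep("signal", n), rep("s", n),
                   if (x$with_offset) "signal"))
}

#' @rdname tidy.pk_exp_fit
#' @export
glance.pk_exp_fit <- function(x, ...) {
  tibble(n_components = x$n_components, n = x$n_points, rss = x$rss,
         sigma = x$sigma,
         flags = paste(x$flags, collapse = ";"))
}

# evaluate a fitted multi-exponential at times t (relative to window start)
predict_exp_fit <- function(x, t) {
  tt <- t - x$window[1]
  rowSums(vapply(seq_len(x$n_components),
                 function(i) x$amplitudes[i] * exp(-tt / x$tau[i]),
                 numeric(length(tt)))) + x$offset
}

#' Amplitude-weighted average time constant
#'
#' \eqn{\tau_{avg} = (a_1\tau_1 + a_2\tau_2)/(a_1 + a_2)}: the summary
#' photostability metric of a biexponential photobleaching fit. Amplitudes
#' may be fractions or percentages (only their ratio matters).
#'
#' @param a1,a2 Component amplitudes (same units).
#' @param tau1,tau2 Component time constants (same units; the result is in
#'   those units).
#' @return Weighted average time constant.
#' @examples
#' weighted_avg_tau(67, 10, 33, 87)  # ~35 ms
#' @export
weighted_avg_tau <- function(a1, tau1, a2, tau2) {
  if (any(a1 + a2 <= 0)) abort("`a1 + a2` must be > 0.")
  (a1 * tau1 + a2 * tau2) / (a1 + a2)
}
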