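#' Percent recovery from pulse-pair readouts
#'
#' \deqn{PR = (FR - FB)/(FL - FB) \times 100} where `FL` and `FB` are the
#' fluorescence levels at the start and end of the first pulse and `FR` the
#' level at the start of the second pulse. Full recovery gives 100, none
#' gives 0.
#'
#' @param FL,FB,FR Signal levels (any common units). Vectorized.
#' @return Percent recovery.
#' @examples
#' percent_recovery(100, 20, 60)  # 50
#' @export
percent_recovery <- function(FL, FB, FR) {
  if (any(FL == FB)) {
    abort("percent recovery is undefined when FL == FB (no decay to recover).")
  }
  (FR - FB) / (FL - FB) * 100
}

#' Fit a ground-state recovery curve
#'
#' Fits percent recovery versus dark time to a single exponential
#' \eqn{PR(t_d) = P_{max}(1 - e^{-t_d/\tau_{gsr}})}. The asymptotic
#' amplitude `P_max` is free by default; set `fix_pmax = 100` (or any value)
#' to constrain it.
#'
#' @param data Data frame with columns `dark_time` (s) and `PR` (percent),
#'   or with `FL`, `FB`, `FR` columns from which `PR` is computed.
#'   Replicate rows per dark time are allowed and are fit together.
#' @param fix_pmax Optional fixed recovery amplitude (percent).
#' @return A `pk_recovery_fit` with elements `tau_gsr` (s), `p_max`, 95%
#'   CIs, and the points used; supports [tidy()], [glance()], [autoplot()].
#' @export
fit_gsr_recovery <- function(data, fix_pmax = NULL) {
  df <- as_tibble(data)
  if (!"PR" %in% names(df)) {
    if (!all(c("FL", "FB", "FR") %in% names(df))) {
      abort("`data` needs either a `PR` column or FL/FB/FR columns.")
    }
    df$PR <- percent_recovery(df$FL, df$FB, df$FR)
  }
  df <- df[is.finite(df$PR) & df$dark_time > 0, ]
  if (nrow(df) < 4) abort("need at least 4 recovery points.")
  if (diff(range(log10(df$dark_time))) < 1) {
    warn("dark times span less than one decade; tau_gsr may be poorly constrained.")
  }

  tau_grid <- 10^seq(log10(min(df$dark_time)), log10(max(df$dark_time)),
                     by = 0.5)
  fits <- purrr::map(tau_grid, function(tau0) {
    st <- if (is.null(fix_pmax)) {
      list(p_max = max(df$PR), tau = tau0)
    } else {
      list(tau = tau0)
    }
    fml <- if (is.null(fix_pmax)) {
      PR ~ p_max * (1 - exp(-dark_time / tau))
    } else {
      stats::as.formula(sprintf("PR ~ %g * (1 - exp(-dark_time / tau))",
                                fix_pmax))
    }
    tryCatch(minpack.lm::nlsLM(fml, data = df, start = st,
                               lower = rep(1e-12, length(st)),
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (!length(fits)) abort("ground-state recovery fit failed to converge.")
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2), 0)
  fit <- fits[[which.min(rss)]]
  cf <- coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  z <- qnorm(0.975)
  se <- if (is.null(vc)) rep(NA_real_, length(cf)) else sqrt(pmax(diag(vc), 0))
  names(se) <- names(cf)
  structure(list(
    tau_gsr = unname(cf[["tau"]]),
    tau_gsr_ci = unname(cf[["tau"]] + c(-1, 1) * z * se[["tau"]]),
    p_max = if (is.null(fix_pmax)) unname(cf[["p_max"]]) else fix_pmax,
    p_max_ci = if (is.null(fix_pmax)) {
      unname(cf[["p_max"]] + c(-1, 1) * z * se[["p_max"]])
    } else {
      c(fix_pmax, fix_pmax)
    },
    rss = min(rss), n = nrow(df), points = df[, c("dark_time", "PR")]),
    class = "pk_recovery_fit")
}

#' @export
print.pk_recovery_fit <- function(x, ...) {
  cat("<ground-state recovery fit>\n")
  cat(sprintf("  tau_gsr = %.4g ms (95%% CI %.4g-%.4g)\n",
              x$tau_gsr * 1e3, x$tau_gsr_ci[1] * 1e3, x$tau_gsr_ci[2] * 1e3))
  cat(sprintf("  P_max   = %.3g%% (95%% CI %.3g-%.3g)\n",
              x$p_max, x$p_max_ci[1], x$p_max_ci[2]))
  invisible(x)
}

#' @export
tidy.pk_recovery_fit <- function(x, ...) {
  tibble(term = c("tau_gsr", "p_max"),
         estimate = c(x$tau_gsr, x$p_max),
         conf.low = c(x$tau_gsr_ci[1], x$p_max_ci[1]),
         conf.high = c(x$tau_gsr_ci[2], x$p_max_ci[2]),
         units = c("s", "percent"))
}

#' @export
glance.pk_recovery_fit <- function(x, ...) {
  tibble(tau_gsr = x$tau_gsr, p_max = x$p_max, rss = x$rss, n = x$n)
}
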