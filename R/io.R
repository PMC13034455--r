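#' Read and write fluorescence traces as CSV with sidecar metadata
#'
#' Traces are written as two-column CSV (`time_s`, `signal`) with a sidecar
#' `<file>.meta` key=value text file carrying the protocol metadata
#' (waveform kind, intensity, pulse timing, noise model, seed).
#'
#' @param trace A `pk_trace` (or any data frame with `time` and `signal`).
#' @param file Output CSV path.
#' @return `write_trace()` returns `file` invisibly; `read_trace()` returns
#'   a `pk_trace` tibble with the metadata (if found) attached.
#' @export
write_trace <- function(trace, file) {
  utils::write.csv(data.frame(time_s = trace$time, signal = trace$signal),
                   file, row.names = FALSE)
  meta <- attr(trace, "meta")
  kv <- character()
  if (!is.null(meta$waveform)) {
    wf <- meta$waveform
    kv <- c(kv, paste0("protocol=", wf$kind),
            paste0("intensity_kw_cm2=", wf$intensity_peak))
    if (!is.null(wf$pulse_width))
      kv <- c(kv, paste0("pulse_width_ms=", wf$pulse_width * 1e3))
    if (!is.null(wf$dark_time))
      kv <- c(kv, paste0("dark_time_ms=", wf$dark_time * 1e3))
    if (!is.null(wf$period))
      kv <- c(kv, paste0("period_ms=", wf$period * 1e3))
  }
  if (!is.null(meta$noise)) {
    kv <- c(kv, paste0("noise=", meta$noise$kind),
            paste0("seed=", meta$noise$seed %||% ""))
  }
  if (!is.null(meta$spec)) kv <- c(kv, paste0("fluorophore=", meta$spec$name))
  if (length(kv)) writeLines(kv, paste0(file, ".meta"))
  invisible(file)
}

#' @rdname write_trace
#' @export
read_trace <- function(file) {
  df <- utils::read.csv(file)
  if (!all(c("time_s", "signal") %in% names(df))) {
    abort("trace CSV must have columns `time_s` and `signal`.")
  }
  tr <- tibble(time = df$time_s, signal = df$signal)
  if (any(diff(tr$time) <= 0)) abort("trace times must be strictly increasing.")
  meta <- list()
  mfile <- paste0(file, ".meta")
  if (file.exists(mfile)) {
    kv <- strsplit(readLines(mfile), "=", fixed = TRUE)
    meta <- setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                     vapply(kv, `[[`, "", 1))
  }
  structure(tr, class = c("pk_trace", class(tr)), meta = meta)
}
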