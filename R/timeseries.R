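#' Uniformly sampled time series
#'
#' Lightweight container for a uniformly sampled signal. The time of sample
#' `n` (1-based) is `t0_s + (n - 1) / fs_hz`.
#'
#' @param values numeric vector of samples.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param t0_s time of the first sample, seconds from session start.
#' @param units unit string, e.g. `"V"`, `"g"`, `"A"`, `"arbitrary"`.
#' @param label channel label, e.g. `"HPL"`.
#' @return an object of class `emu_ts`.
#' @export
emu_ts <- function(values, fs_hz, t0_s = 0, units = "V", label = "") {
  stopifnot(is.numeric(values), length(fs_hz) == 1, fs_hz > 0)
  structure(
    list(values = as.numeric(values), fs_hz = as.numeric(fs_hz),
         t0_s = as.numeric(t0_s), units = as.character(units),
         label = as.character(label)),
    class = "emu_ts")
}

#' Sample times of a time series
#'
#' @param ts an `emu_ts`.
#' @return numeric vector of sample times in seconds.
#' @export
ts_times <- function(ts) {
  stopifnot(inherits(ts, "emu_ts"))
  ts$t0_s + (seq_along(ts$values) - 1) / ts$fs_hz
}

#' Duration of a time series in seconds
#' @param ts an `emu_ts`.
#' @return length of the sampled span in seconds (`n / fs`).
#' @export
ts_duration <- function(ts) length(ts$values) / ts$fs_hz

#' @export
print.emu_ts <- function(x, ...) {
  cat(sprintf("<emu_ts> %s: %d samples @ %g Hz, t0 = %g s, units = %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$values), x$fs_hz, x$t0_s, x$units))
  invisible(x)
}

#' @export
length.emu_ts <- function(x) length(x$values)
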