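# Detector parameter-surface scans: synthetic noiseless traces probe the
# operating thresholds of the SD detector directly in its decision domain.
# Because the detector decides on the 0.5 Hz low-passed trace, the swept
# quantities are constructed there: excursions are linearly rescaled (onset
# scan) or offset-corrected (offset scan) so that the achieved decision
# variable equals the swept grid value, not merely the nominal ramp depth
# (zero-phase filtering reshapes fast ramps, including a step-response
# overshoot of several percent).

#' Scan the SD onset threshold
#'
#' Generates noiseless DC-coupled traces containing a single negative
#' excursion whose maximum 3 s look-back drop (measured on the low-passed
#' trace, the detector's decision variable) equals each swept depth, runs
#' the detector at the given parameters, and returns the smallest depth that
#' yields a detection.
#'
#' @param depths_mv swept drop depths in mV (default 5 to 10 by 0.1).
#' @param fs_hz sampling rate (default 1000).
#' @param params an [sd_params()].
#' @return list with `fired` (logical per depth), `depths_mv`, and
#'   `threshold_mv` (smallest firing depth, `NA` if none fired).
#' @export
scan_sd_onset_threshold <- function(depths_mv = seq(5, 10, by = 0.1),
                                    fs_hz = 1000, params = sd_params()) {
  fs <- fs_hz
  # unit excursion: 30 s baseline, 5 s raised-cosine fall, 30 s plateau
  unit <- c(rep(0, 30 * fs), -rcos_ramp(5 * fs), rep(-1, 30 * fs))
  filt <- lowpass(emu_ts(unit, fs), params$lowpass_cutoff_hz)$values
  k <- round(params$lookback_s * fs)
  m <- max(filt[1:(length(filt) - k)] - filt[(k + 1):length(filt)])
  max_drop <- function(x) {
    f <- lowpass(emu_ts(x, fs), params$lowpass_cutoff_hz)$values
    max(f[1:(length(f) - k)] - f[(k + 1):length(f)])
  }
  fired <- vapply(depths_mv, function(d) {
    amp <- (d / 1000) / m
    # one multiplicative correction pins the achieved low-passed drop to the
    # grid value (recursive-filter round-off breaks exact scaling at ~1e-7
    # relative)
    amp <- amp * (d / 1000) / max_drop(amp * unit)
    nrow(detect_sd(emu_ts(amp * unit, fs, label = "scan"), params)) > 0
  }, logical(1))
  list(fired = fired, depths_mv = depths_mv,
       threshold_mv = if (any(fired)) min(depths_mv[fired]) else NA_real_)
}

#' Scan the SD offset recovery margin
#'
#' Generates noiseless synthetic SD excursions (35 mV deep) that recover to
#' a plateau a swept number of mV above the detected onset potential
#' (achieved level measured on the low-passed trace and corrected to the
#' grid value), and returns the smallest plateau level at which the detector
#' emits an offset before trace end (event not truncated).
#'
#' @param levels_mv swept recovery levels in mV above the onset potential
#'   (default 0.5 to 4 by 0.1).
#' @param fs_hz sampling rate (default 1000).
#' @param params an [sd_params()].
#' @param amplitude_v excursion depth in volts (default 0.035).
#' @return list with `offset_found` (logical per level), `levels_mv`, and
#'   `margin_mv` (smallest level with an offset, `NA` if none).
#' @export
scan_sd_offset_margin <- function(levels_mv = seq(0.5, 4, by = 0.1),
                                  fs_hz = 1000, params = sd_params(),
                                  amplitude_v = 0.035) {
  fs <- fs_hz
  base <- function(plateau_v) {
    c(rep(0, 40 * fs),
      -amplitude_v * rcos_ramp(8 * fs),
      rep(-amplitude_v, 20 * fs),
      -amplitude_v + (plateau_v + amplitude_v) * rcos_ramp(15 * fs),
      rep(plateau_v, 60 * fs))
  }
  # probe: recovery to baseline fixes the onset potential (which depends
  # only on the fall segment)
  probe <- detect_sd(emu_ts(base(0), fs, label = "scan"), params)
  stopifnot(nrow(probe) == 1)
  p <- probe$onset_potential_v
  tail_idx <- function(x) seq(length(x) - 30 * fs, length(x) - 10 * fs)
  offset_found <- vapply(levels_mv, function(lv) {
    target <- p + lv / 1000
    raw <- base(target)
    filt <- lowpass(emu_ts(raw, fs), params$lowpass_cutoff_hz)$values
    achieved <- mean(filt[tail_idx(filt)])
    # one additive correction pins the achieved plateau to the grid value
    raw <- base(target + (target - achieved))
    ev <- detect_sd(emu_ts(raw, fs, label = "scan"), params)
    nrow(ev) >= 1 && !ev$truncated[1]
  }, logical(1))
  list(offset_found = offset_found, levels_mv = levels_mv,
       margin_mv = if (any(offset_found)) min(levels_mv[offset_found])
                   else NA_real_)
}
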