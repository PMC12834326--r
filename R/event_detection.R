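# Detectors for the DC-coupled analysis stack: spreading depolarization
# (SD), seizure counting, cardiac R-peaks / RR intervals, and state-of-
# vigilance (SOV) scoring. Detection conventions:
#   SD: 0.5 Hz low-passed DC-coupled trace; onset = downward crossing of a
#       7.5 mV threshold relative to the value 3 s before; offset = upward
#       crossing of (onset potential + 2 mV).
#   Seizures: counted when longer than 10 s and spaced >= 10 min apart.
#   R peaks: 15-125 Hz bandpass, local maxima above an adaptive threshold.
#   SOV: REM = theta (4-7 Hz) spectral peak; NREM = maximal delta
#        (0.5-4 Hz) power without acceleration; WAKE = accelerometer activity.

# Numerical guard for threshold comparisons (1 nV): makes boundary decisions
# invariant to the low-pass filter's double-precision round-off (its DC gain
# differs from 1 by ~4e-6 relative before normalisation); far below any
# physical signal level.
EPS_V <- 1e-9

#' Default spreading-depolarization detector parameters
#'
#' `onset_drop_v` 7.5 mV drop relative to the value `lookback_s` = 3 s
#' before; `offset_margin_v` 2 mV recovery above the onset potential;
#' `lowpass_cutoff_hz` 0.5 Hz pre-filter.
#'
#' @param onset_drop_v onset threshold in volts (default 0.0075).
#' @param lookback_s look-back span in seconds (default 3).
#' @param offset_margin_v offset margin above onset potential in volts
#'   (default 0.002).
#' @param lowpass_cutoff_hz low-pass cutoff applied before detection
#'   (default 0.5 Hz).
#' @return list of class `sd_params`.
#' @export
sd_params <- function(onset_drop_v = 0.0075, lookback_s = 3.0,
                      offset_margin_v = 0.002, lowpass_cutoff_hz = 0.5) {
  stopifnot(onset_drop_v > 0, lookback_s > 0, offset_margin_v > 0,
            lowpass_cutoff_hz > 0)
  structure(list(onset_drop_v = onset_drop_v, lookback_s = lookback_s,
                 offset_margin_v = offset_margin_v,
                 lowpass_cutoff_hz = lowpass_cutoff_hz),
            class = "sd_params")
}

#' Detect spreading depolarizations on a DC-coupled trace
#'
#' Low-passes the trace at `params$lowpass_cutoff_hz`, then marks an onset at
#' the first sample whose drop relative to the value `lookback_s` earlier
#' reaches `onset_drop_v`, while the detector is armed. The offset is the
#' first later sample at or above (onset potential + `offset_margin_v`);
#' events still open at the end of the trace are emitted with the offset at
#' trace end and `truncated = TRUE`. The detector re-arms after each offset.
#'
#' @param ts DC-coupled [emu_ts()] in volts. The detector assumes the DC
#'   component is intact; AC-coupled traces cannot carry the SD shift.
#' @param params an [sd_params()].
#' @return data.frame of class `sd_events`: `channel`, `onset_s`, `offset_s`,
#'   `onset_potential_v` (potential at onset, referenced by the offset rule),
#'   `min_potential_v`, `amplitude_v` (baseline-to-trough: the pre-onset
#'   look-back value minus the minimum), `duration_s`, `truncated`.
#' @export
detect_sd <- function(ts, params = sd_params()) {
  stopifnot(inherits(ts, "emu_ts"), inherits(params, "sd_params"))
  fs <- ts$fs_hz
  k <- round(params$lookback_s * fs)
  if (k < 1) stop("sampling rate too low for the ", params$lookback_s,
                  " s look-back (fs*lookback < 1)")
  if (length(ts$values) <= k) stop("trace shorter than the look-back span")
  x <- lowpass(ts, params$lowpass_cutoff_hz)$values
  n <- length(x)
  drop <- x[(k + 1):n] - x[1:(n - k)]          # x(t) - x(t - lookback)
  onset_ok <- drop <= -(params$onset_drop_v - EPS_V)
  ev <- list()
  i <- 1L
  while (i <= length(onset_ok)) {
    if (onset_ok[i]) {
      onset_idx <- i + k                        # index into x
      thr <- x[onset_idx] + params$offset_margin_v
      rest <- if (onset_idx < n) x[(onset_idx + 1):n] else numeric(0)
      hit <- which(rest >= thr - EPS_V)
      truncated <- length(hit) == 0
      offset_idx <- if (truncated) n else onset_idx + hit[1]
      seg <- x[onset_idx:offset_idx]
      # amplitude is baseline-to-trough: referenced to the look-back value
      # (the pre-onset potential), not the onset potential, which already
      # sits one onset threshold below baseline when the detector fires
      ev[[length(ev) + 1L]] <- data.frame(
        channel = ts$label,
        onset_s = ts$t0_s + (onset_idx - 1) / fs,
        offset_s = ts$t0_s + (offset_idx - 1) / fs,
        onset_potential_v = x[onset_idx],
        min_potential_v = min(seg),
        amplitude_v = x[onset_idx - k] - min(seg),
        duration_s = (offset_idx - onset_idx) / fs,
        truncated = truncated)
      i <- offset_idx - k + 1L                  # re-arm after the offset
    } else {
      i <- i + 1L
    }
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(channel = character(0), onset_s = numeric(0),
               offset_s = numeric(0), onset_potential_v = numeric(0),
               min_potential_v = numeric(0), amplitude_v = numeric(0),
               duration_s = numeric(0), truncated = logical(0))
  class(out) <- c("sd_events", "data.frame")
  out
}

#' Detect seizure candidate intervals from band power
#'
#' Per channel, computes 9-16 Hz band power (mean square of the band-passed
#' signal) in 1 s windows and opens a candidate when power exceeds
#' `k_thresh` times a rolling median baseline for at least two consecutive
#' windows, closing it after two consecutive windows below. Overlapping
#' candidates from different channels are merged, pooling their channel sets.
#'
#' @param channels list of [emu_ts()] (one per channel).
#' @param band two-element frequency band in Hz (default `c(9, 16)`).
#' @param window_s analysis window in seconds (default 1).
#' @param k_thresh threshold multiple of the baseline (default 5).
#' @param baseline_s rolling-median baseline span in seconds (default 300).
#' @return data.frame with `onset_s`, `offset_s`, `channels`
#'   (comma-separated labels), sorted by onset. Zero rows on quiet input.
#' @export
detect_seizure_candidates <- function(channels, band = c(9, 16),
                                      window_s = 1.0, k_thresh = 5,
                                      baseline_s = 300) {
  if (inherits(channels, "emu_ts")) channels <- list(channels)
  stopifnot(length(channels) >= 1)
  per_chan <- lapply(channels, function(ch) {
    if (ch$fs_hz <= 2 * band[2])
      stop("sampling rate must exceed twice the upper band edge")
    bp <- bandpass(ch, band[1], band[2])
    nw <- as.integer(round(ch$fs_hz * window_s))
    nwin <- length(bp$values) %/% nw
    pw <- colMeans(matrix(bp$values[seq_len(nw * nwin)]^2, nrow = nw))
    # rolling median baseline (odd window, in analysis-window units)
    kmed <- min(2L * (as.integer(baseline_s / window_s) %/% 2L) + 1L,
                2L * ((nwin - 1L) %/% 2L) + 1L)
    base <- if (kmed >= 3) stats::runmed(pw, kmed, endrule = "median")
            else rep(stats::median(pw), nwin)
    above <- pw > k_thresh * base
    intervals_from_flags(above, min_run = 2L, min_gap = 2L,
                         window_s = window_s, t0_s = ch$t0_s,
                         label = ch$label)
  })
  cand <- do.call(rbind, per_chan)
  if (is.null(cand) || nrow(cand) == 0)
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      channels = character(0)))
  merge_overlapping(cand[order(cand$onset_s), , drop = FALSE])
}

# Turn a logical per-window flag vector into intervals, requiring min_run
# consecutive TRUE windows to open and min_gap consecutive FALSE to close.
intervals_from_flags <- function(flags, min_run, min_gap, window_s, t0_s,
                                 label) {
  out <- list()
  n <- length(flags)
  i <- 1L
  while (i <= n - min_run + 1L) {
    if (all(flags[i:(i + min_run - 1L)])) {
      j <- i + min_run - 1L
      below <- 0L
      while (j < n && below < min_gap) {
        j <- j + 1L
        below <- if (flags[j]) 0L else below + 1L
      }
      end <- if (below >= min_gap) j - min_gap else j
      out[[length(out) + 1L]] <- data.frame(
        onset_s = t0_s + (i - 1) * window_s,
        offset_s = t0_s + end * window_s,
        channels = label)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(out)) do.call(rbind, out) else NULL
}

merge_overlapping <- function(cand) {
  out <- cand[1, , drop = FALSE]
  if (nrow(cand) > 1) for (r in 2:nrow(cand)) {
    last <- nrow(out)
    if (cand$onset_s[r] <= out$offset_s[last]) {
      out$offset_s[last] <- max(out$offset_s[last], cand$offset_s[r])
      labs <- union(strsplit(out$channels[last], ",")[[1]],
                    strsplit(cand$channels[r], ",")[[1]])
      out$channels[last] <- paste(sort(labs), collapse = ",")
    } else out <- rbind(out, cand[r, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Consolidate seizure candidates into counted events
#'
#' Candidates closer than `min_gap_s` (gap measured from one candidate's
#' offset to the next one's onset) are merged into a single event spanning
#' both; merged events whose duration does not exceed `min_duration_s` are
#' discarded. The defaults implement the counting rule: only events longer
#' than 10 s, spaced at least 10 min apart, are counted.
#'
#' @param candidates data.frame with `onset_s`, `offset_s` (and optionally
#'   `channels`), sorted by onset.
#' @param min_duration_s minimum counted duration, exclusive (default 10).
#' @param min_gap_s minimum spacing between counted events (default 600).
#' @return data.frame of class `seizure_events`: `onset_s`, `offset_s`,
#'   `duration_s`, `channels_involved`.
#' @export
consolidate_seizures <- function(candidates, min_duration_s = 10,
                                 min_gap_s = 600) {
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0),
                      channels_involved = character(0))
  class(empty) <- c("seizure_events", "data.frame")
  if (is.null(candidates) || nrow(candidates) == 0) return(empty)
  if (is.unsorted(candidates$onset_s))
    stop("candidates must be sorted by onset")
  if (is.null(candidates$channels)) candidates$channels <- ""
  merged <- candidates[1, c("onset_s", "offset_s", "channels"), drop = FALSE]
  if (nrow(candidates) > 1) for (r in 2:nrow(candidates)) {
    last <- nrow(merged)
    if (candidates$onset_s[r] - merged$offset_s[last] < min_gap_s) {
      merged$offset_s[last] <- max(merged$offset_s[last],
                                   candidates$offset_s[r])
      labs <- union(strsplit(merged$channels[last], ",")[[1]],
                    strsplit(candidates$channels[r], ",")[[1]])
      merged$channels[last] <- paste(sort(labs), collapse = ",")
    } else merged <- rbind(merged,
                           candidates[r, c("onset_s", "offset_s", "channels")])
  }
  merged$duration_s <- merged$offset_s - merged$onset_s
  keep <- merged[merged$duration_s > min_duration_s, , drop = FALSE]
  out <- data.frame(onset_s = keep$onset_s, offset_s = keep$offset_s,
                    duration_s = keep$duration_s,
                    channels_involved = keep$channels)
  rownames(out) <- NULL
  class(out) <- c("seizure_events", "data.frame")
  out
}

#' Detect ECG R-peak times
#'
#' Band-passes the cardiac signal at 15-125 Hz, auto-detects R-wave polarity
#' from the skewness of the filtered trace, and returns the times of local
#' maxima exceeding an adaptive threshold (a rolling quantile of the
#' rectified signal), separated by a 60 ms refractory period.
#'
#' @param ecg an [emu_ts()] (a warning is raised below 250 Hz sampling).
#' @param band bandpass edges in Hz (default `c(15, 125)`).
#' @param refractory_s refractory period in seconds (default 0.06, which
#'   supports rat rates up to 1000 bpm).
#' @param quantile_win_s rolling window for the adaptive threshold (default
#'   10 s).
#' @param thresh_frac threshold as a fraction of the rolling 99.9th
#'   percentile (default 0.5).
#' @return numeric vector of strictly increasing peak times in seconds.
#' @export
detect_r_peaks <- function(ecg, band = c(15, 125), refractory_s = 0.06,
                           quantile_win_s = 10, thresh_frac = 0.5) {
  stopifnot(inherits(ecg, "emu_ts"))
  fs <- ecg$fs_hz
  if (fs < 250) warning("sampling rate below 250 Hz; R-peak timing degrades")
  x <- bandpass(ecg, band[1], band[2])$values
  if (all(x == 0)) return(numeric(0))
  # polarity: R waves dominate the heavy tail of the filtered trace
  skew <- mean((x - mean(x))^3)
  if (skew < 0) x <- -x
  n <- length(x)
  # adaptive threshold: per-block 99.9th percentile, linearly interpolated
  blk <- max(1L, as.integer(round(quantile_win_s * fs)))
  starts <- seq(1L, n, by = blk)
  q <- vapply(starts, function(s)
    stats::quantile(x[s:min(s + blk - 1L, n)], 0.999, names = FALSE),
    numeric(1))
  thr_blk <- thresh_frac * q
  floor_thr <- 5 * stats::mad(x)
  thr <- if (length(starts) > 1) {
    stats::approx(starts + blk / 2, thr_blk, xout = seq_len(n),
                  rule = 2)$y
  } else rep(thr_blk, n)
  thr <- pmax(thr, floor_thr)
  cand <- which(x > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[x[cand] > x[cand - 1] & x[cand] >= x[cand + 1]]
  if (!length(cand)) return(numeric(0))
  # enforce refractory, keeping the larger peak
  ref <- refractory_s * fs
  keep <- integer(0)
  last_i <- -Inf
  for (i in cand) {
    if (i - last_i >= ref) {
      keep <- c(keep, i); last_i <- i
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i; last_i <- i
    }
  }
  ecg$t0_s + (keep - 1) / fs
}

#' RR intervals from R-peak times
#'
#' First differences of the peak times.
#'
#' @param peaks strictly increasing numeric vector of R-peak times (s).
#' @return list of class `rr_series` with `peak_times_s` and `rr_s`.
#' @export
rr_intervals <- function(peaks) {
  if (length(peaks) >= 2 && any(diff(peaks) <= 0))
    stop("peak times must be strictly increasing")
  structure(list(peak_times_s = as.numeric(peaks),
                 rr_s = diff(as.numeric(peaks))),
            class = "rr_series")
}

#' Score state of vigilance (wake / NREM / REM)
#'
#' Epoch-wise scoring: WAKE when median windowed acceleration power exceeds
#' the wake threshold (default 3x the 20th percentile of the session's
#' acceleration power); otherwise REM when the theta (4-7 Hz) to delta
#' (0.5-4 Hz) band-power ratio exceeds `r_rem` and the spectral argmax over
#' 0.5-12 Hz lies in the theta band; otherwise NREM when the argmax lies in
#' the delta band; otherwise UNSCORED.
#'
#' @param lfp hippocampal [emu_ts()] (DC or AC coupled; band powers are
#'   computed from the epoch periodogram).
#' @param acc_power 1-per-window acceleration power [emu_ts()] from
#'   [acc_rms_power()], covering the same span.
#' @param epoch_s epoch length in seconds (default 10).
#' @param r_rem theta/delta ratio threshold for REM (default 1.5).
#' @param wake_quantile,wake_mult wake threshold = `wake_mult` x the
#'   `wake_quantile` quantile of `acc_power` (defaults 0.2 and 3).
#' @return data.frame of class `hypnogram`: `t_start_s`, `t_end_s`, `state`;
#'   epochs tile the scored span contiguously.
#' @export
classify_sov <- function(lfp, acc_power, epoch_s = 10, r_rem = 1.5,
                         wake_quantile = 0.2, wake_mult = 3) {
  stopifnot(inherits(lfp, "emu_ts"), inherits(acc_power, "emu_ts"))
  if (abs(lfp$t0_s - acc_power$t0_s) > 1 / acc_power$fs_hz ||
      abs(ts_duration(lfp) - ts_duration(acc_power)) > epoch_s)
    stop("LFP and acceleration power spans are misaligned")
  fs <- lfp$fs_hz
  ne <- as.integer(floor(ts_duration(lfp) / epoch_s))
  if (ne < 1) stop("input shorter than one epoch")
  wake_thr <- wake_mult *
    stats::quantile(acc_power$values, wake_quantile, names = FALSE)
  nse <- as.integer(round(epoch_s * fs))                 # samples per epoch
  nwe <- as.integer(round(epoch_s * acc_power$fs_hz))    # acc windows/epoch
  states <- character(ne)
  for (e in seq_len(ne)) {
    acc_med <- stats::median(
      acc_power$values[((e - 1) * nwe + 1):min(e * nwe,
                                               length(acc_power$values))])
    if (acc_med > wake_thr) { states[e] <- "WAKE"; next }
    seg <- emu_ts(lfp$values[((e - 1) * nse + 1):(e * nse)], fs)
    sp <- welch_psd(seg, window_samples = min(2048L, nse))
    f <- sp$freqs_hz; p <- sp$power
    band_pow <- function(lo, hi) sum(p[f >= lo & f <= hi])
    theta <- band_pow(4, 7); delta <- band_pow(0.5, 4)
    scope <- which(f >= 0.5 & f <= 12)
    fmax <- f[scope[which.max(p[scope])]]
    states[e] <- if (delta > 0 && theta / delta > r_rem &&
                     fmax >= 4 && fmax <= 7) "REM"
                 else if (fmax >= 0.5 && fmax <= 4) "NREM"
                 else "UNSCORED"
  }
  out <- data.frame(t_start_s = lfp$t0_s + (seq_len(ne) - 1) * epoch_s,
                    t_end_s = lfp$t0_s + seq_len(ne) * epoch_s,
                    state = states)
  class(out) <- c("hypnogram", "data.frame")
  out
}

#' Order spreading-depolarization onsets across channels
#'
#' For events belonging to one SD episode (onsets within `group_window_s` of
#' the earliest), returns channels sorted by onset with delays relative to
#' the earliest onset; ties are broken by channel label order.
#'
#' @param events an `sd_events` data.frame pooled across channels.
#' @param group_window_s grouping window in seconds (default 120).
#' @return data.frame with `channel`, `onset_s`, `delay_s`, sorted by onset
#'   then label.
#' @export
sd_propagation_order <- function(events, group_window_s = 120) {
  if (is.null(events) || nrow(events) == 0)
    return(data.frame(channel = character(0), onset_s = numeric(0),
                      delay_s = numeric(0)))
  first <- min(events$onset_s)
  grp <- events[events$onset_s - first <= group_window_s, , drop = FALSE]
  grp <- grp[order(grp$onset_s, grp$channel), , drop = FALSE]
  data.frame(channel = grp$channel, onset_s = grp$onset_s,
             delay_s = grp$onset_s - first, row.names = NULL)
}
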