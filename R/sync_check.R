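# Video/electrophysiology synchronization check. Two independent actigraphy
# series -- one from video frame intensities, one from the head-mounted
# accelerometer -- are computed on 1 s windows, high-pass filtered at 10 mHz,
# and cross-correlated; on a synchronized rig the correlation peaks at
# 0 +/- 1 s.

#' Actigraphy from video frame intensity
#'
#' Per 1 s window, the mean of the absolute first time-derivative of pixel
#' intensity: `mean(|I(f) - I(f-1)|)` over the frames in the window. Accepts
#' a frame-mean intensity series; for full-frame stacks reduce each frame to
#' its per-pixel |delta| mean first (see `frame_stack_actigraphy`).
#'
#' @param frame_intensity an [emu_ts()] of frame-mean intensity at the video
#'   frame rate.
#' @param window_s window length in seconds (default 1).
#' @return list of class `actigraphy` with `values` (one per window),
#'   `window_s`, `t0_s`, `source = "VIDEO"`.
#' @export
video_actigraphy <- function(frame_intensity, window_s = 1.0) {
  stopifnot(inherits(frame_intensity, "emu_ts"))
  fps <- frame_intensity$fs_hz
  if (fps < 2 / window_s)
    stop("frame rate too low: need >= ", 2 / window_s, " fps")
  d <- abs(diff(frame_intensity$values))
  # derivative at frame f uses frames f-1 and f; assign it to frame f
  nw <- as.integer(round(fps * window_s))
  nwin <- length(d) %/% nw
  if (nwin < 1) stop("too few frames for one window")
  vals <- colMeans(matrix(d[seq_len(nw * nwin)], nrow = nw))
  structure(list(values = vals, window_s = window_s,
                 t0_s = frame_intensity$t0_s, source = "VIDEO"),
            class = "actigraphy")
}

#' Actigraphy from a full-frame stack
#'
#' Averages `|I(x, y, f) - I(x, y, f-1)|` over pixels first, then windows;
#' the per-pixel mode of the video actigraphy.
#'
#' @param frames numeric array (height x width x frames).
#' @param fps frame rate in Hz.
#' @param window_s window length in seconds.
#' @param t0_s time of the first frame.
#' @return an `actigraphy` (source `"VIDEO"`).
#' @export
frame_stack_actigraphy <- function(frames, fps, window_s = 1.0, t0_s = 0) {
  stopifnot(length(dim(frames)) == 3)
  nf <- dim(frames)[3]
  dmean <- vapply(seq_len(nf - 1), function(f)
    mean(abs(frames[, , f + 1] - frames[, , f])), numeric(1))
  # feed the per-frame |delta| means through the same windowing; prepend the
  # first value so diff() reproduces dmean exactly
  video_actigraphy(emu_ts(cumsum(c(0, dmean)), fps, t0_s,
                          units = "arbitrary", label = "video"),
                   window_s)
}

#' Actigraphy from head-mounted acceleration
#'
#' Delegates to [acc_rms_power()] (2-125 Hz band, 1 s windows).
#'
#' @param acc list of three [emu_ts()] axes.
#' @param window_s window length in seconds.
#' @return an `actigraphy` (source `"ACCEL"`).
#' @export
accel_actigraphy <- function(acc, window_s = 1.0) {
  p <- acc_rms_power(acc, window_s = window_s)
  structure(list(values = p$values, window_s = window_s, t0_s = p$t0_s,
                 source = "ACCEL"),
            class = "actigraphy")
}

#' Cross-correlation lag between two actigraphy series
#'
#' High-passes both series at `highpass_hz` (default 10 mHz, first-order
#' forward-backward), removes the mean, and computes the normalized
#' (Pearson-style) cross-correlation on the common 1 s window grid over lags
#' `|l| <= max_lag_s`. A positive lag means `b` lags `a` (b's content occurs
#' later). The 1 s grid bounds lag resolution at +/- 1 window.
#'
#' @param a,b `actigraphy` objects with overlapping spans.
#' @param max_lag_s maximum lag searched, seconds (default 120).
#' @param highpass_hz high-pass cutoff in Hz (default 0.01).
#' @return list with `lag_s`, `peak_correlation`, and the full `lags_s` /
#'   `correlation` function.
#' @export
sync_lag <- function(a, b, max_lag_s = 120, highpass_hz = 0.01) {
  stopifnot(inherits(a, "actigraphy"), inherits(b, "actigraphy"),
            a$window_s == b$window_s)
  w <- a$window_s
  t_lo <- max(a$t0_s, b$t0_s)
  t_hi <- min(a$t0_s + length(a$values) * w, b$t0_s + length(b$values) * w)
  n_overlap <- floor((t_hi - t_lo) / w)
  if (n_overlap < 10 * max_lag_s / w)
    stop("insufficient overlap: ", n_overlap, " windows < 10*max_lag")
  ai <- as.integer(round((t_lo - a$t0_s) / w))
  bi <- as.integer(round((t_lo - b$t0_s) / w))
  xa <- a$values[(ai + 1):(ai + n_overlap)]
  xb <- b$values[(bi + 1):(bi + n_overlap)]
  fs <- 1 / w
  hp <- butter_sos(1, min(highpass_hz / (fs / 2), 0.99), type = "high")
  pad <- pad_samples(fs, highpass_hz)
  xa <- zerophase(xa, hp, pad); xa <- xa - mean(xa)
  xb <- zerophase(xb, hp, pad); xb <- xb - mean(xb)
  max_k <- as.integer(round(max_lag_s / w))
  denom <- sqrt(sum(xa^2) * sum(xb^2))
  lags <- seq(-max_k, max_k)
  cc <- vapply(lags, function(k) {
    # positive k: correlate a(t) with b(t + k) -> b lags a
    if (k >= 0) sum(xa[seq_len(n_overlap - k)] * xb[seq_len(n_overlap - k) + k])
    else sum(xa[seq_len(n_overlap + k) - k] * xb[seq_len(n_overlap + k)])
  }, numeric(1)) / denom
  best <- which.max(cc)
  list(lag_s = lags[best] * w, peak_correlation = cc[best],
       lags_s = lags * w, correlation = cc)
}
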