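# Filtering and spectral primitives following the rig's analysis conventions:
# 0.5-125 Hz bandpass for field potentials, Welch PSD with 2048-sample
# windows, 1 s non-overlapping spectrogram / acceleration-power windows after
# a 2-125 Hz bandpass. All filters are 4th-order Butterworth applied
# forward-backward (zero phase) so detector onset times are not delayed.

# Butterworth design as a cascade of second-order sections (biquads).
# The expanded-polynomial form is numerically unusable at the cutoffs this
# rig works at (0.5 Hz on 1 kHz data is a normalized cutoff of 1e-3: the
# poles cluster near z = 1 and the direct-form recursion loses ~7 digits);
# the biquad cascade keeps round-off near machine precision. Analog
# prototype poles are bilinear-transformed per conjugate pair and each
# section is gain-normalized exactly at its reference frequency (DC for
# low-pass, Nyquist for high-pass).
butter_sos <- function(order, wn, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 1, wn > 0, wn < 1)
  wc <- tan(pi * wn / 2)                       # pre-warped analog cutoff
  k <- seq_len(order)
  s <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # prototype poles
  pa <- if (type == "low") wc * s else wc / s
  z <- (1 + pa) / (1 - pa)                     # bilinear transform
  pair_idx <- which(Im(z) > 1e-14)
  real_idx <- which(abs(Im(z)) <= 1e-14)
  sections <- list()
  for (p in z[pair_idx]) {
    den <- c(1, -2 * Re(p), Mod(p)^2)
    if (type == "low") {
      g <- sum(den) / 4                        # H(1) = 1
      sections[[length(sections) + 1]] <- list(b = g * c(1, 2, 1), a = den)
    } else {
      g <- (den[1] - den[2] + den[3]) / 4      # H(-1) = 1
      sections[[length(sections) + 1]] <- list(b = g * c(1, -2, 1), a = den)
    }
  }
  for (p in Re(z[real_idx])) {
    den <- c(1, -p, 0)
    if (type == "low") {
      g <- (1 - p) / 2
      sections[[length(sections) + 1]] <- list(b = g * c(1, 1, 0), a = den)
    } else {
      g <- (1 + p) / 2
      sections[[length(sections) + 1]] <- list(b = g * c(1, -1, 0), a = den)
    }
  }
  sections
}

# One biquad, direct form: MA part vectorised, AR part via the C recursion
# in stats::filter.
biquad_apply <- function(sec, x) {
  n <- length(x)
  b <- sec$b; a <- sec$a
  v <- b[1] * x + b[2] * c(0, x[-n]) + b[3] * c(0, 0, x[-c(n - 1, n)])
  if (a[3] == 0 && a[2] == 0) return(v)
  as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
}

sos_apply <- function(sos, x) {
  for (sec in sos) x <- biquad_apply(sec, x)
  x
}

sos_dc_gain <- function(sos) {
  prod(vapply(sos, function(s) sum(s$b) / sum(s$a), numeric(1)))
}

# Zero-phase (forward-backward) filter with odd-mirror reflection padding
# and offset removal: starting both passes from zero state would leave long
# edge transients at cutoffs far below Nyquist, so the signal is reflected
# about its endpoints and shifted to start at zero; the offset is restored
# through the cascade's squared DC gain (1 for low-pass, 0 for high-pass).
zerophase <- function(x, sos, pad) {
  n <- length(x)
  if (n < 4) return(x)
  pad <- min(pad, n - 1)
  xp <- if (pad > 0) {
    c(2 * x[1] - x[seq(pad + 1, 2)], x, 2 * x[n] - x[seq(n - 1, n - pad)])
  } else x
  c0 <- xp[1]
  y <- rev(sos_apply(sos, rev(sos_apply(sos, xp - c0))))
  y <- y + c0 * sos_dc_gain(sos)^2
  y[seq(pad + 1, pad + n)]
}

# Pad length heuristic: a few time constants of the slowest edge.
pad_samples <- function(fs_hz, lowest_edge_hz) {
  if (!is.finite(lowest_edge_hz) || lowest_edge_hz <= 0) return(1000L)
  as.integer(min(ceiling(3 * fs_hz / lowest_edge_hz), 1e6))
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward-backward. `lo_hz = 0` degenerates to
#' a low-pass; `hi_hz = Inf` degenerates to a high-pass. The field-potential
#' convention is 0.5-125 Hz.
#'
#' @param ts an [emu_ts()].
#' @param lo_hz lower band edge in Hz (0 for low-pass).
#' @param hi_hz upper band edge in Hz (`Inf` for high-pass).
#' @param order filter order (default 4).
#' @return filtered `emu_ts`, same length, units preserved.
#' @export
bandpass <- function(ts, lo_hz, hi_hz, order = 4) {
  stopifnot(inherits(ts, "emu_ts"))
  nyq <- ts$fs_hz / 2
  if (lo_hz < 0 || (is.finite(hi_hz) && hi_hz >= nyq) || lo_hz >= hi_hz)
    stop("band edges must satisfy 0 <= lo < hi < fs/2 (lo_hz=", lo_hz,
         ", hi_hz=", hi_hz, ", fs/2=", nyq, ")")
  if (lo_hz == 0 && !is.finite(hi_hz)) return(ts)
  # a band-pass is applied as cascaded high-pass and low-pass halves with
  # the edges as -3 dB points (a single direct band-pass design is not
  # numerically viable at edges far below Nyquist, e.g. 0.5-4 Hz at 1 kHz)
  edge <- if (lo_hz > 0) lo_hz else hi_hz
  pad <- pad_samples(ts$fs_hz, edge)
  x <- ts$values
  if (lo_hz > 0)
    x <- zerophase(x, butter_sos(order, lo_hz / nyq, type = "high"), pad)
  if (is.finite(hi_hz))
    x <- zerophase(x, butter_sos(order, hi_hz / nyq, type = "low"), pad)
  out <- ts
  out$values <- x
  out
}

#' Zero-phase Butterworth low-pass filter
#'
#' Convenience wrapper over [bandpass()] with `lo_hz = 0`. The DC-coupled SD
#' convention is a 0.5 Hz cutoff.
#'
#' @inheritParams bandpass
#' @param cutoff_hz cutoff frequency in Hz.
#' @return filtered `emu_ts`.
#' @export
lowpass <- function(ts, cutoff_hz, order = 4) bandpass(ts, 0, cutoff_hz, order)

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-tapered segments of
#' `window_samples` samples with 50% overlap, one-sided density scaling so
#' that `sum(power) * df` approximates the signal variance.
#'
#' @param ts an [emu_ts()].
#' @param window_samples segment length (default 2048).
#' @return list of class `emu_spectrum` with `freqs_hz`, `power`
#'   (units^2/Hz), `window_len_samples`, `method_tag`.
#' @export
welch_psd <- function(ts, window_samples = 2048) {
  stopifnot(inherits(ts, "emu_ts"))
  x <- ts$values
  nw <- as.integer(window_samples)
  if (length(x) < nw)
    stop("input shorter than one window (", length(x), " < ", nw, ")")
  hop <- nw %/% 2L
  starts <- seq(1L, length(x) - nw + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / nw)  # periodic Hann
  seg <- matrix(x[outer(seq_len(nw) - 1L, starts, "+")], nrow = nw)
  seg <- seg * w
  spec <- Mod(stats::mvfft(seg))^2
  nf <- nw %/% 2L + 1L
  p <- rowMeans(spec[seq_len(nf), , drop = FALSE])
  scale <- 1 / (ts$fs_hz * sum(w^2))
  p <- p * scale
  # one-sided: double all bins except DC (and Nyquist when nw is even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nw %% 2L == 0L) dbl[nf] <- 1
  structure(
    list(freqs_hz = (seq_len(nf) - 1) * ts$fs_hz / nw,
         power = p * dbl,
         window_len_samples = nw,
         method_tag = "welch-hann-50pct"),
    class = "emu_spectrum")
}

#' Short-time spectrogram on non-overlapping windows
#'
#' Periodogram (Hann-tapered) of consecutive non-overlapping windows of
#' `window_s` seconds, matching the 1 s acceleration-power windows.
#'
#' @param ts an [emu_ts()].
#' @param window_s window length in seconds (default 1).
#' @return list of class `emu_spectrogram` with `times_s` (window centres),
#'   `freqs_hz`, `power` (time x frequency matrix) and `window_s`.
#' @export
spectrogram <- function(ts, window_s = 1.0) {
  stopifnot(inherits(ts, "emu_ts"))
  nw <- as.integer(round(ts$fs_hz * window_s))
  if (nw < 8) stop("window too short: fs * window_s must be >= 8")
  nwin <- length(ts$values) %/% nw
  if (nwin < 1) stop("input shorter than one window")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / nw)
  seg <- matrix(ts$values[seq_len(nw * nwin)], nrow = nw)
  seg <- seg * w
  spec <- Mod(stats::mvfft(seg))^2
  nf <- nw %/% 2L + 1L
  scale <- 1 / (ts$fs_hz * sum(w^2))
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nw %% 2L == 0L) dbl[nf] <- 1
  structure(
    list(times_s = ts$t0_s + (seq_len(nwin) - 0.5) * window_s,
         freqs_hz = (seq_len(nf) - 1) * ts$fs_hz / nw,
         power = t(spec[seq_len(nf), , drop = FALSE] * scale * dbl),
         window_s = window_s),
    class = "emu_spectrogram")
}

#' Windowed RMS power of tri-axis acceleration
#'
#' Band-passes each axis (default 2-125 Hz), forms the vector magnitude, and
#' returns the root-mean-square per non-overlapping window (default 1 s).
#'
#' @param acc list of three [emu_ts()] (x, y, z), equal length and rate.
#' @param window_s window length in seconds.
#' @param band two-element band in Hz.
#' @return `emu_ts` at `1/window_s` Hz, units `g (rms)`; one value per
#'   window, timestamped at the window start.
#' @export
acc_rms_power <- function(acc, window_s = 1.0, band = c(2, 125)) {
  stopifnot(is.list(acc), length(acc) == 3)
  lens <- vapply(acc, function(a) length(a$values), integer(1))
  if (length(unique(lens)) != 1) stop("acceleration axes differ in length")
  fs <- acc[[1]]$fs_hz
  # the 125 Hz upper edge assumes the rig's 1 kHz rate; at lower sampling
  # rates it is clamped below Nyquist
  hi <- min(band[2], 0.45 * fs)
  filt <- lapply(acc, bandpass, lo_hz = band[1], hi_hz = hi)
  mag2 <- filt[[1]]$values^2 + filt[[2]]$values^2 + filt[[3]]$values^2
  nw <- as.integer(round(fs * window_s))
  nwin <- length(mag2) %/% nw
  rms <- sqrt(colMeans(matrix(mag2[seq_len(nw * nwin)], nrow = nw)))
  emu_ts(rms, fs_hz = 1 / window_s, t0_s = acc[[1]]$t0_s,
         units = paste0(acc[[1]]$units, " (rms)"), label = "acc_power")
}
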