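# Independent oracles used across tests. Each is written against the rule
# definitions, not against the package's implementation path.

# Two's-complement byte oracle via bit operations (independent of the
# arithmetic encoder in the package).
oracle_int24_be <- function(code) {
  u <- bitwAnd(as.integer(code), 0xFFFFFF)
  c(bitwAnd(bitwShiftR(u, 16L), 0xFF),
    bitwAnd(bitwShiftR(u, 8L), 0xFF),
    bitwAnd(u, 0xFF))
}
oracle_int16_le <- function(code) {
  u <- bitwAnd(as.integer(code), 0xFFFF)
  c(bitwAnd(u, 0xFF), bitwAnd(bitwShiftR(u, 8L), 0xFF))
}

# Direct application of the seizure counting rule: walk the sorted list,
# merge any candidate whose onset is within min_gap of the current event's
# offset, then drop events not longer than min_dur.
oracle_consolidate <- function(onsets, offsets, min_dur = 10, min_gap = 600) {
  stopifnot(length(onsets) == length(offsets))
  if (length(onsets) == 0)
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  ev_on <- onsets[1]; ev_off <- offsets[1]
  out_on <- numeric(0); out_off <- numeric(0)
  for (i in seq_along(onsets)[-1]) {
    if (onsets[i] - ev_off < min_gap) {
      ev_off <- max(ev_off, offsets[i])
    } else {
      out_on <- c(out_on, ev_on); out_off <- c(out_off, ev_off)
      ev_on <- onsets[i]; ev_off <- offsets[i]
    }
  }
  out_on <- c(out_on, ev_on); out_off <- c(out_off, ev_off)
  keep <- (out_off - out_on) > min_dur
  data.frame(onset_s = out_on[keep], offset_s = out_off[keep])
}

# Brute-force counter gap audit: explicit pairwise modular differences.
oracle_counter_gaps <- function(counters) {
  pos <- integer(0); missing <- numeric(0)
  for (i in seq_along(counters)[-1]) {
    d <- (counters[i] - counters[i - 1]) %% 2^24
    if (d != 1) {
      pos <- c(pos, i)
      missing <- c(missing, (d - 1) %% 2^24)
    }
  }
  data.frame(position = pos, missing = missing)
}

# Brute-force SD onset oracle: naive loop over the low-passed trace applying
# the look-back rule sample by sample.
oracle_sd_onset_index <- function(x_filtered, fs, drop_v = 0.0075,
                                  lookback_s = 3) {
  k <- round(lookback_s * fs)
  for (t in (k + 1):length(x_filtered)) {
    if (x_filtered[t] - x_filtered[t - k] <= -(drop_v - 1e-9)) return(t)
  }
  NA_integer_
}

# 1/f-ish stationary noise: white noise shaped by a single-pole AR filter.
make_pink_noise <- function(n, alpha = 0.95) {
  as.numeric(stats::filter(stats::rnorm(n), alpha, method = "recursive"))
}

# Random valid packet for round-trip properties.
random_packet <- function() {
  emu_packet(counter = sample(0:(2^24 - 1), 1),
             chan_codes_afe1 = sample(seq(-2^23, 2^23 - 1), 8),
             chan_codes_afe2 = sample(seq(-2^23, 2^23 - 1), 8),
             accel_codes = sample(seq(-2^15, 2^15 - 1), 3),
             status_afe1 = as.raw(sample(0:255, 3, replace = TRUE)),
             status_afe2 = as.raw(sample(0:255, 3, replace = TRUE)))
}

# Minimal hand-built session (bypassing the simulator) for format tests.
fake_session <- function(values_by_label, acc_values, fs) {
  n <- length(values_by_label[[1]])
  structure(list(
    lfp = lapply(stats::setNames(names(values_by_label),
                                 names(values_by_label)),
                 function(l) emu_ts(values_by_label[[l]], fs, units = "V",
                                    label = l)),
    acc = lapply(1:3, function(ax) emu_ts(acc_values, fs, units = "g")),
    ecg = NULL, cpa = NULL, video_intensity = NULL,
    truth = NULL,
    cfg = list(fs_hz = fs, duration_s = n / fs)),
    class = "emu_session")
}
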