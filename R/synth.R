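# Seeded synthetic multimodal session generator. Emulates the phenomenology
# the detectors are built for: state-dependent hippocampal rhythms (delta in
# NREM, ~6 Hz theta in REM, broadband in wake), seizures (sentinel spike,
# 9-16 Hz spike burst, ~5 mV DC shift), spreading depolarizations (negative
# DC excursions of >= 20 mV lasting 30-60 s with per-channel propagation
# delays), ECG as an R-peak impulse train convolved with a QRS kernel,
# state-dependent head acceleration, CPA current with state-dependent means,
# and a video-intensity stream coupled to the same movement process. Every
# stream draws from its own substream of the master seed, so adding a
# modality never perturbs the others. No biophysical realism is claimed:
# these are test harness signals with exactly known ground truth.

sub_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 1009 + id * 7919) %% 2147483647)
}

#' Build a synthetic-session scenario
#'
#' Defaults encode the study conditions the detectors target: SD amplitude
#' 35 mV and duration 45 s (within the 30-60 s range), seizure spike bursts
#' at 12 Hz inside the 9-16 Hz band with a 5 mV DC shift, rat-typical 6 Hz
#' heart rate, and a REM > NREM ordering of CPA state means.
#'
#' @param duration_s session length in seconds.
#' @param fs_hz electrophysiology sampling rate (default 1000).
#' @param channels LFP/ECoG channel labels.
#' @param sov_schedule data.frame with `state`, `t_start_s`, `t_end_s`
#'   tiling the session, or `NULL` for a repeating wake/NREM/REM cycle
#'   (120 s / 180 s / 60 s).
#' @param seizures data.frame with `onset_s`, `duration_s`, `burst_freq_hz`,
#'   `amplitude_v`, `dc_shift_v` (zero rows for none).
#' @param sds list of SD episodes, each a list with `onset_s`, `amplitude_v`
#'   (>= 0.02), `duration_s` (30-60), `channel_delays_s` (named vector of
#'   per-channel onset delays; channels absent from it carry no SD).
#' @param ecg list with `rate_hz` (default 6) and `arrhythmia` (data.frame
#'   with `after_s`, `rr_s`: at the first beat after `after_s`, one interval
#'   of `rr_s` is inserted); `NULL` disables the ECG stream.
#' @param cpa list with `state_mean_na` (named WAKE/NREM/REM) and `noise_na`;
#'   `NULL` disables the CPA stream.
#' @param video list with `frame_rate` (Hz) and `movement_gain`; `NULL`
#'   disables the video-intensity stream.
#' @param clock_skew_s clock skew planted on the video stream (the video
#'   clock runs behind the electrophysiology clock by this much; its content
#'   appears delayed).
#' @param seed master RNG seed (required for reproducibility).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(duration_s,
                            fs_hz = 1000,
                            channels = c("HPL", "HAL", "HAR", "HPR"),
                            sov_schedule = NULL,
                            seizures = NULL,
                            sds = NULL,
                            ecg = list(rate_hz = 6, arrhythmia = NULL),
                            cpa = list(state_mean_na =
                                         c(WAKE = 51, NREM = 50, REM = 52),
                                       noise_na = 0.2),
                            video = list(frame_rate = 20,
                                         movement_gain = 50),
                            clock_skew_s = 0,
                            seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  stopifnot(duration_s > 0, fs_hz > 0, length(channels) >= 1)
  if (is.null(sov_schedule)) {
    cyc <- data.frame(state = c("WAKE", "NREM", "REM"),
                      dur = c(120, 180, 60))
    reps <- ceiling(duration_s / sum(cyc$dur))
    st <- rep(cyc$state, reps)
    du <- rep(cyc$dur, reps)
    ends <- cumsum(du)
    keep <- which(ends - du < duration_s)
    sov_schedule <- data.frame(state = st[keep],
                               t_start_s = (ends - du)[keep],
                               t_end_s = pmin(ends[keep], duration_s))
  }
  if (is.null(seizures))
    seizures <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                           burst_freq_hz = numeric(0),
                           amplitude_v = numeric(0), dc_shift_v = numeric(0))
  if (nrow(seizures)) {
    if (is.null(seizures$burst_freq_hz)) seizures$burst_freq_hz <- 12
    if (is.null(seizures$amplitude_v)) seizures$amplitude_v <- 5e-4
    if (is.null(seizures$dc_shift_v)) seizures$dc_shift_v <- 0.005
    if (any(seizures$burst_freq_hz < 9 | seizures$burst_freq_hz > 16))
      stop("seizure burst frequency must lie in 9-16 Hz")
    if (any(seizures$onset_s + seizures$duration_s > duration_s))
      stop("seizure extends past the session end")
  }
  if (!is.null(sds)) for (sd in sds) {
    if (sd$amplitude_v < 0.02)
      stop("SD amplitude below the physiologic 20 mV floor")
    if (sd$duration_s < 30 || sd$duration_s > 60)
      stop("SD duration must lie in 30-60 s")
    if (sd$onset_s + max(sd$channel_delays_s) + sd$duration_s + 30 >
        duration_s)
      stop("SD (incl. recovery) extends past the session end")
    if (!all(names(sd$channel_delays_s) %in% channels))
      stop("SD channel_delays_s names must be session channels")
  }
  structure(list(duration_s = duration_s, fs_hz = fs_hz,
                 channels = channels, sov_schedule = sov_schedule,
                 seizures = seizures, sds = if (is.null(sds)) list() else sds,
                 ecg = ecg, cpa = cpa, video = video,
                 clock_skew_s = clock_skew_s, seed = as.integer(seed)),
            class = "scenario_config")
}

# Raised-cosine ramp from 0 to 1 over n samples.
rcos_ramp <- function(n) (1 - cos(pi * seq_len(n) / n)) / 2

# Canonical SD excursion: raised-cosine fall (fall_s), plateau, exponential
# recovery towards baseline. Returns the waveform (negative excursion of
# depth `amplitude_v`) sampled at fs; length covers duration + recovery tail.
sd_waveform <- function(amplitude_v, duration_s, fs, fall_s = 5,
                        recover_tau_s = 8) {
  n_fall <- round(fall_s * fs)
  n_plateau <- round(max(duration_s - fall_s, 5) * fs)
  n_rec <- round(6 * recover_tau_s * fs)
  c(-amplitude_v * rcos_ramp(n_fall),
    rep(-amplitude_v, n_plateau),
    -amplitude_v * exp(-seq_len(n_rec) / (recover_tau_s * fs)))
}

band_noise <- function(n, fs, lo, hi, sd_target) {
  x <- stats::rnorm(n)
  y <- bandpass(emu_ts(x, fs), lo, hi)$values
  y * sd_target / stats::sd(y)
}

#' Simulate a multimodal session with ground truth
#'
#' Deterministic given the scenario seed. Returns every stream as an
#' [emu_ts()] plus a ground-truth ledger against which the detectors are
#' scored.
#'
#' @param cfg a [scenario_config()].
#' @return list of class `emu_session`: `lfp` (named list of channels, V),
#'   `acc` (list of 3 axes, g), `ecg` (V or NULL), `cpa` (nA or NULL),
#'   `video_intensity` (arbitrary units at the frame rate, or NULL),
#'   `truth` (list: `seizures`, `sds`, `sov`, `r_peaks_s`,
#'   `cpa_state_means`, `clock_skew_s`), and `cfg`.
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  fs <- cfg$fs_hz
  n <- round(cfg$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  sched <- cfg$sov_schedule

  # per-sample state index
  state_of_t <- character(n)
  for (b in seq_len(nrow(sched))) {
    i0 <- floor(sched$t_start_s[b] * fs) + 1
    i1 <- min(round(sched$t_end_s[b] * fs), n)
    if (i0 <= i1) state_of_t[i0:i1] <- sched$state[b]
  }

  # ---- LFP channels -------------------------------------------------------
  lfp <- list()
  sd_truth <- list()
  for (ci in seq_along(cfg$channels)) {
    ch <- cfg$channels[ci]
    set.seed(sub_seed(cfg$seed, 100 + ci))
    x <- band_noise(n, fs, 0.5, 45, 30e-6)       # broadband floor
    for (b in seq_len(nrow(sched))) {
      i0 <- floor(sched$t_start_s[b] * fs) + 1
      i1 <- min(round(sched$t_end_s[b] * fs), n)
      idx <- i0:i1
      x[idx] <- x[idx] + switch(sched$state[b],
        NREM = band_noise(length(idx), fs, 0.5, 4, 150e-6),
        REM = 150e-6 * sin(2 * pi * 6 * tt[idx] +
                             stats::runif(1, 0, 2 * pi)) +
              band_noise(length(idx), fs, 4, 30, 20e-6),
        WAKE = band_noise(length(idx), fs, 2, 50, 80e-6))
    }
    # seizures: sentinel spike, rhythmic burst, small negative DC shift
    if (nrow(cfg$seizures)) for (s in seq_len(nrow(cfg$seizures))) {
      sz <- cfg$seizures[s, ]
      i0 <- round(sz$onset_s * fs) + 1
      i1 <- min(round((sz$onset_s + sz$duration_s) * fs), n)
      idx <- i0:i1
      env <- rep(1, length(idx))
      ramp <- min(round(fs), length(idx) %/% 4)
      env[seq_len(ramp)] <- rcos_ramp(ramp)
      env[length(idx) + 1 - seq_len(ramp)] <- rcos_ramp(ramp)
      x[idx] <- x[idx] + sz$amplitude_v * env *
        sin(2 * pi * sz$burst_freq_hz * tt[idx])
      # sentinel spike: one 40 ms biphasic discharge at onset
      spk <- round(0.04 * fs)
      if (i0 + spk <= n)
        x[i0:(i0 + spk)] <- x[i0:(i0 + spk)] +
          2 * sz$amplitude_v * sin(pi * seq_len(spk + 1) / (spk + 1))
      # DC shift: raised-cosine edged negative plateau
      dc <- rep(-sz$dc_shift_v, length(idx))
      edge <- min(round(2 * fs), length(idx) %/% 3)
      dc[seq_len(edge)] <- -sz$dc_shift_v * rcos_ramp(edge)
      dc[length(idx) + 1 - seq_len(edge)] <- -sz$dc_shift_v * rcos_ramp(edge)
      x[idx] <- x[idx] + dc
    }
    # spreading depolarizations with per-channel delays
    for (sd in cfg$sds) {
      if (!(ch %in% names(sd$channel_delays_s))) next
      onset <- sd$onset_s + sd$channel_delays_s[[ch]]
      wf <- sd_waveform(sd$amplitude_v, sd$duration_s, fs)
      i0 <- round(onset * fs) + 1
      i1 <- min(i0 + length(wf) - 1, n)
      x[i0:i1] <- x[i0:i1] + wf[seq_len(i1 - i0 + 1)]
      sd_truth[[length(sd_truth) + 1]] <- data.frame(
        channel = ch, onset_s = onset,
        offset_s = onset + sd$duration_s,
        amplitude_v = sd$amplitude_v)
    }
    lfp[[ch]] <- emu_ts(x, fs, units = "V", label = ch)
  }

  # ---- acceleration -------------------------------------------------------
  set.seed(sub_seed(cfg$seed, 200))
  acc <- lapply(1:3, function(ax) {
    env <- rep(0.002, n)                        # sensor noise floor, g
    env[state_of_t == "WAKE"] <- 0.05           # movement bouts
    if (any(state_of_t == "REM")) {             # brief muscle twitches
      rem_idx <- which(state_of_t == "REM")
      runs <- split(rem_idx, cumsum(c(1, diff(rem_idx) != 1)))
      for (r in runs) {
        tw_starts <- r[1] + round(seq(2, length(r) / fs - 1, by = 10) * fs)
        for (s0 in tw_starts) {
          s1 <- min(s0 + round(0.5 * fs), r[length(r)])
          env[s0:s1] <- 0.03
        }
      }
    }
    if (nrow(cfg$seizures)) for (s in seq_len(nrow(cfg$seizures))) {
      i0 <- round(cfg$seizures$onset_s[s] * fs) + 1
      i1 <- min(round((cfg$seizures$onset_s[s] +
                         cfg$seizures$duration_s[s]) * fs), n)
      env[i0:i1] <- 0.15                        # convulsive burst
    }
    emu_ts(stats::rnorm(n) * env, fs, units = "g",
           label = c("acc_x", "acc_y", "acc_z")[ax])
  })
  # shared movement envelope (drives the video stream)
  move_env <- rep(0.002, n)
  move_env[state_of_t == "WAKE"] <- 0.05
  if (nrow(cfg$seizures)) for (s in seq_len(nrow(cfg$seizures))) {
    i0 <- round(cfg$seizures$onset_s[s] * fs) + 1
    i1 <- min(round((cfg$seizures$onset_s[s] +
                       cfg$seizures$duration_s[s]) * fs), n)
    move_env[i0:i1] <- 0.15
  }

  # ---- ECG ----------------------------------------------------------------
  ecg_ts <- NULL; r_peaks <- numeric(0)
  if (!is.null(cfg$ecg)) {
    set.seed(sub_seed(cfg$seed, 300))
    rr0 <- 1 / cfg$ecg$rate_hz
    t_beat <- 0.5
    while (t_beat < cfg$duration_s - 0.5) {
      r_peaks <- c(r_peaks, t_beat)
      rr <- rr0
      if (!is.null(cfg$ecg$arrhythmia) && nrow(cfg$ecg$arrhythmia)) {
        hit <- which(t_beat >= cfg$ecg$arrhythmia$after_s &
                     t_beat - rr0 < cfg$ecg$arrhythmia$after_s)
        if (length(hit)) rr <- cfg$ecg$arrhythmia$rr_s[hit[1]]
      }
      t_beat <- t_beat + rr
    }
    r_peaks <- round(r_peaks * fs) / fs         # snap to the sample grid
    x <- stats::rnorm(n) * 2e-5                 # baseline noise, V
    half <- round(0.008 * fs)                   # QRS half-width 8 ms
    kern <- 8e-4 * cos(pi * seq(-half, half) / (2 * half))^2
    for (tp in r_peaks) {
      i0 <- round(tp * fs) + 1 - half
      ii <- i0:(i0 + 2 * half)
      ok <- ii >= 1 & ii <= n
      x[ii[ok]] <- x[ii[ok]] + kern[ok]
    }
    ecg_ts <- emu_ts(x, fs, units = "V", label = "ECG")
  }

  # ---- CPA current --------------------------------------------------------
  cpa_ts <- NULL
  if (!is.null(cfg$cpa)) {
    set.seed(sub_seed(cfg$seed, 400))
    mu <- cfg$cpa$state_mean_na[state_of_t]
    ar <- stats::filter(stats::rnorm(n) * cfg$cpa$noise_na * 0.05,
                        0.999, method = "recursive")
    cpa_ts <- emu_ts(as.numeric(mu + ar), fs, units = "nA", label = "CPA")
  }

  # ---- video intensity ----------------------------------------------------
  video_ts <- NULL
  if (!is.null(cfg$video)) {
    set.seed(sub_seed(cfg$seed, 500))
    fps <- cfg$video$frame_rate
    nf <- round(cfg$duration_s * fps)
    # frame f shows the scene at (frame time - clock skew)
    t_frame <- (seq_len(nf) - 1) / fps - cfg$clock_skew_s
    src <- pmin(pmax(round(t_frame * fs) + 1, 1), n)
    env_f <- move_env[src]
    env_f[t_frame < 0 | t_frame > cfg$duration_s] <- 0.002
    dI <- cfg$video$movement_gain * env_f * stats::rnorm(nf)
    video_ts <- emu_ts(100 + cumsum(dI), fps, units = "arbitrary",
                       label = "video")
  }

  truth <- list(
    seizures = cfg$seizures[, c("onset_s", "duration_s"), drop = FALSE],
    sds = if (length(sd_truth)) do.call(rbind, sd_truth) else
      data.frame(channel = character(0), onset_s = numeric(0),
                 offset_s = numeric(0), amplitude_v = numeric(0)),
    sov = sched,
    r_peaks_s = r_peaks,
    cpa_state_means = if (is.null(cfg$cpa)) NULL else cfg$cpa$state_mean_na,
    clock_skew_s = cfg$clock_skew_s)

  structure(list(lfp = lfp, acc = acc, ecg = ecg_ts, cpa = cpa_ts,
                 video_intensity = video_ts, truth = truth, cfg = cfg),
            class = "emu_session")
}

#' Export a simulated session to hourly wire-format files
#'
#' Converts physical units back to raw codes with the header's gain/vref and
#' accelerometer full scale, packs them into 63-byte packets with a
#' continuous wrapping counter, and rotates files on the hour boundary of
#' elapsed samples. LFP/ECoG channels are matched to header labels; an
#' `"ECG"` header label takes the ECG stream; a `"CPA"` label takes the CPA
#' current converted to a sense voltage via `cpa_sense_r_ohm`. Unmatched
#' header channels are zero-filled. Samples beyond full scale are saturated
#' and counted.
#'
#' @param session an `emu_session` from [simulate_session()].
#' @param header an [emu_header()]; its `sample_rate_hz` must match the
#'   session.
#' @param dir output directory (created if needed).
#' @param cpa_sense_r_ohm sense resistance used to map CPA current (nA) to a
#'   recorded voltage (default 1e5: 50 nA -> 5 mV).
#' @return list with `files` (paths in time order) and `n_saturated`.
#' @export
export_session <- function(session, header, dir,
                           cpa_sense_r_ohm = 1e5) {
  stopifnot(inherits(session, "emu_session"), inherits(header, "emu_header"))
  fs <- session$cfg$fs_hz
  if (header$sample_rate_hz != fs)
    stop("header sample rate (", header$sample_rate_hz,
         ") does not match session (", fs, ")")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- round(session$cfg$duration_s * fs)
  volts <- matrix(0, nrow = 16, ncol = n)
  for (ch in names(session$lfp)) {
    slot <- match(ch, header$channel_labels)
    if (!is.na(slot)) volts[slot, ] <- session$lfp[[ch]]$values
  }
  if (!is.null(session$ecg)) {
    slot <- match("ECG", header$channel_labels)
    if (!is.na(slot)) volts[slot, ] <- session$ecg$values
  }
  if (!is.null(session$cpa)) {
    slot <- match("CPA", header$channel_labels)
    if (!is.na(slot))
      volts[slot, ] <- session$cpa$values * 1e-9 * cpa_sense_r_ohm
  }
  n_sat <- 0
  codes <- matrix(0, nrow = 16, ncol = n)
  for (r in 1:16) {
    gain <- header$afe_gain[if (r <= 8) 1 else 2]
    vc <- volts_to_code(volts[r, ], gain, header$vref_volts)
    codes[r, ] <- vc$code
    n_sat <- n_sat + vc$n_saturated
  }
  acc_codes <- matrix(0, nrow = 3, ncol = n)
  for (ax in 1:3) {
    gc <- g_to_accel_code(session$acc[[ax]]$values, header$accel_full_scale_g)
    acc_codes[ax, ] <- gc$code
    n_sat <- n_sat + gc$n_saturated
  }
  counters <- (seq_len(n) - 1) %% 2^24
  per_file <- fs * 3600
  files <- character(0)
  k0 <- 1
  hour <- 0
  while (k0 <= n) {
    k1 <- min(k0 + per_file - 1, n)
    idx <- k0:k1
    bytes <- rbind(
      int24_to_be(counters[idx]),
      matrix(0, nrow = 3, ncol = length(idx)),       # status AFE1
      int24_to_be_mat(codes[1:8, idx, drop = FALSE]),
      matrix(0, nrow = 3, ncol = length(idx)),       # status AFE2
      int24_to_be_mat(codes[9:16, idx, drop = FALSE]),
      int16_to_le_mat(acc_codes[, idx, drop = FALSE]))
    h <- header
    h$start_time_utc <- header$start_time_utc + hour * 3600
    path <- file.path(dir, hourly_file_name(h$rig_id, h$start_time_utc))
    write_hourly_file(h, as.raw(bytes), path)
    files <- c(files, path)
    k0 <- k1 + 1
    hour <- hour + 1
  }
  list(files = files, n_saturated = n_sat)
}

#' Decode the channels of wire-format files into physical units
#'
#' Reads one or more hourly files (in time order), audits counter
#' continuity, and converts every channel to volts and the acceleration to
#' g. The inverse of [export_session()] up to quantization (<= 1/2 LSB per
#' sample).
#'
#' @param paths character vector of `.emu` file paths in time order.
#' @return list with `header`, `channels` (named list of [emu_ts()] in V),
#'   `acc` (list of 3 [emu_ts()] in g), `gaps` (counter audit), and
#'   `fragment_bytes`.
#' @export
decode_file_channels <- function(paths) {
  stopifnot(length(paths) >= 1)
  recs <- lapply(paths, read_hourly_file, as_packets = FALSE)
  header <- recs[[1]]$header
  chan <- do.call(cbind, lapply(recs, function(r)
    t(cbind(r$data$chan1, r$data$chan2))))
  accm <- do.call(rbind, lapply(recs, function(r) r$data$accel))
  counters <- do.call(c, lapply(recs, function(r) r$data$counter))
  fs <- header$sample_rate_hz
  channels <- lapply(1:16, function(r) {
    gain <- header$afe_gain[if (r <= 8) 1 else 2]
    emu_ts(code_to_volts(chan[r, ], gain, header$vref_volts), fs,
           units = "V", label = header$channel_labels[r])
  })
  names(channels) <- header$channel_labels
  acc <- lapply(1:3, function(ax)
    emu_ts(accel_code_to_g(accm[, ax], header$accel_full_scale_g), fs,
           units = "g", label = c("acc_x", "acc_y", "acc_z")[ax]))
  list(header = header, channels = channels, acc = acc,
       gaps = check_counter_continuity(counters),
       fragment_bytes = sum(vapply(recs, function(r) r$fragment_bytes,
                                   numeric(1))))
}
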