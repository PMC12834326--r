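fs <- 1000

sd_trace <- function(depth_v = 0.035, fall_s = 10, plateau_s = 30,
                     rec_s = 20, pre_s = 60, post_s = 30) {
  c(rep(0, pre_s * fs),
    seq(0, -depth_v, length.out = fall_s * fs),
    rep(-depth_v, plateau_s * fs),
    seq(-depth_v, 0, length.out = rec_s * fs),
    rep(0, post_s * fs))
}

test_that("SD detector finds a single planted excursion where the rule fires", {
  expect_equal(nrow(detect_sd(emu_ts(rep(0, 100 * fs), fs))), 0)
  x <- sd_trace()
  ev <- detect_sd(emu_ts(x, fs, label = "HPL"))
  expect_equal(nrow(ev), 1)
  # onset agrees with a naive sample-scan oracle on the low-passed trace
  xf <- lowpass(emu_ts(x, fs), 0.5)$values
  onset_oracle <- oracle_sd_onset_index(xf, fs)
  expect_equal(ev$onset_s, (onset_oracle - 1) / fs)
  # linear ramp at 3.5 mV/s: the 3 s-lookback drop reaches 7.5 mV about
  # 2.1 s into the ramp (a slower 1.75 mV/s ramp saturates the look-back at
  # 5.25 mV and, correctly, never fires)
  expect_gt(ev$onset_s, 60)
  expect_lt(ev$onset_s, 60 + 4)
  slow <- sd_trace(fall_s = 20)
  expect_equal(nrow(detect_sd(emu_ts(slow, fs))), 0)
  # offset during recovery at the first crossing of onset potential + 2 mV
  thr <- ev$onset_potential_v + 0.002
  off_idx <- round(ev$offset_s * fs) + 1
  expect_gte(xf[off_idx], thr - 1e-8)
  expect_lt(xf[off_idx - 1], thr)
  expect_false(ev$truncated)
  expect_equal(ev$amplitude_v, 0.035, tolerance = 0.02)
  expect_equal(ev$duration_s, ev$offset_s - ev$onset_s)
})

test_that("separate SD excursions yield separate events at the 30-60 s scale", {
  one <- sd_trace(post_s = 0)
  x <- c(one, rep(0, 120 * fs), one, rep(0, 30 * fs))
  ev <- detect_sd(emu_ts(x, fs, label = "HPL"))
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$duration_s > 25 & ev$duration_s < 75))
  expect_true(all(ev$amplitude_v > 0))
  expect_true(all(ev$offset_s > ev$onset_s))
})

test_that("seizure-scale 5 mV DC shifts never trigger the SD detector", {
  x <- sd_trace(depth_v = 0.005, fall_s = 2, plateau_s = 20, rec_s = 2)
  expect_equal(nrow(detect_sd(emu_ts(x, fs))), 0)
})

test_that("SD events cut by end of trace are flagged truncated", {
  x <- c(rep(0, 60 * fs), seq(0, -0.035, length.out = 10 * fs),
         rep(-0.035, 30 * fs))                      # never recovers
  ev <- detect_sd(emu_ts(x, fs))
  expect_equal(nrow(ev), 1)
  expect_true(ev$truncated)
  expect_equal(ev$offset_s, (length(x) - 1) / fs)
  expect_error(detect_sd(emu_ts(rep(0, 100), 0.1)), "look-back")
})

test_that("seizure candidates fire on planted bursts, not noise or off-band", {
  set.seed(31)
  n <- 600 * fs
  pink <- make_pink_noise(n)
  pink <- 1e-4 * pink / sd(pink)
  quiet <- detect_seizure_candidates(emu_ts(pink, fs, label = "HPL"))
  expect_equal(nrow(quiet), 0)
  # planted 12 Hz burst at 10x baseline band power for 30 s
  t <- (seq_len(n) - 1) / fs
  bandp <- bandpass(emu_ts(pink, fs), 9, 16)$values
  burst_amp <- sqrt(10 * mean(bandp^2)) * sqrt(2)
  x <- pink
  idx <- t >= 300 & t < 330
  x[idx] <- x[idx] + burst_amp * sin(2 * pi * 12 * t[idx])
  cand <- detect_seizure_candidates(emu_ts(x, fs, label = "HPL"))
  expect_equal(nrow(cand), 1)
  overlap <- min(cand$offset_s, 330) - max(cand$onset_s, 300)
  expect_gte(overlap / 30, 0.9)
  # same burst at 40 Hz sits outside the 9-16 Hz criterion
  y <- pink
  y[idx] <- y[idx] + burst_amp * sin(2 * pi * 40 * t[idx])
  expect_equal(nrow(detect_seizure_candidates(emu_ts(y, fs, label = "HPL"))),
               0)
})

test_that("seizure consolidation applies the >10 s and >=10 min rules", {
  expect_equal(nrow(consolidate_seizures(
    data.frame(onset_s = numeric(0), offset_s = numeric(0)))), 0)
  cand <- data.frame(onset_s = c(0, 180, 2000),
                     offset_s = c(60, 240, 2100))
  ev <- consolidate_seizures(cand)
  expect_equal(ev$onset_s, c(0, 2000))
  expect_equal(ev$offset_s, c(240, 2100))
  # a 9 s candidate is discarded
  expect_equal(nrow(consolidate_seizures(
    data.frame(onset_s = 0, offset_s = 9))), 0)
  expect_error(consolidate_seizures(
    data.frame(onset_s = c(10, 0), offset_s = c(20, 5))), "sorted")
})

test_that("consolidation matches the direct-rule oracle on random lists", {
  set.seed(32)
  for (i in 1:200) {
    n <- sample(0:12, 1)
    on <- sort(runif(n, 0, 7200))
    off <- on + runif(n, 1, 900)
    off <- pmin(off, c(on[-1], Inf) - 0.001)  # keep candidates disjoint
    got <- consolidate_seizures(data.frame(onset_s = on, offset_s = off))
    want <- oracle_consolidate(on, off)
    expect_equal(got$onset_s, want$onset_s)
    expect_equal(got$offset_s, want$offset_s)
    if (nrow(got) > 1) {
      expect_true(all(got$onset_s[-1] - got$offset_s[-nrow(got)] >= 600))
    }
    expect_true(all(got$duration_s > 10))
  }
})

test_that("R peaks are recovered to sample precision from synthetic ECG", {
  expect_length(detect_r_peaks(emu_ts(rep(0, 10 * fs), fs)), 0)
  cfg <- scenario_config(duration_s = 120, seed = 33, channels = "HPL",
                         cpa = NULL, video = NULL,
                         ecg = list(rate_hz = 6, arrhythmia = NULL))
  ses <- simulate_session(cfg)
  peaks <- detect_r_peaks(ses$ecg)
  truth <- ses$truth$r_peaks_s
  expect_lt(abs(length(peaks) - length(truth)), 3)
  m <- min(length(peaks), length(truth))
  expect_lt(max(abs(peaks[seq_len(m)] - truth[seq_len(m)])), 0.005)
})

test_that("a planted long-RR arrhythmia is recovered within 5 ms", {
  cfg <- scenario_config(duration_s = 120, seed = 34, channels = "HPL",
                         cpa = NULL, video = NULL,
                         ecg = list(rate_hz = 6,
                                    arrhythmia = data.frame(after_s = 60,
                                                            rr_s = 0.5)))
  ses <- simulate_session(cfg)
  expect_equal(max(diff(ses$truth$r_peaks_s)), 0.5)
  rr <- rr_intervals(detect_r_peaks(ses$ecg))
  expect_lt(abs(max(rr$rr_s) - 0.5), 0.005)
})

test_that("RR intervals are first differences with an exact sum rule", {
  rr <- rr_intervals(c(0.0, 0.2, 0.4))
  expect_equal(rr$rr_s, c(0.2, 0.2))
  expect_length(rr_intervals(1.5)$rr_s, 0)
  rr2 <- rr_intervals(c(0, 0.167, 0.667))
  expect_equal(rr2$rr_s, c(0.167, 0.5))
  set.seed(35)
  pk <- cumsum(runif(50, 0.1, 0.3))
  rr3 <- rr_intervals(pk)
  expect_equal(sum(rr3$rr_s), pk[50] - pk[1])
  expect_true(all(rr3$rr_s > 0))
  expect_error(rr_intervals(c(0.2, 0.1)), "increasing")
})

test_that("SOV scoring follows the delta/theta/acceleration rules", {
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  quiet_acc <- emu_ts(rep(1e-4, 60), 1, units = "g (rms)")
  # delta-dominated epoch + no acceleration -> NREM
  nrem <- classify_sov(emu_ts(1e-4 * sin(2 * pi * 2 * t), fs), quiet_acc)
  expect_true(all(nrem$state == "NREM"))
  # theta-dominated epoch + near-zero acceleration -> REM
  rem <- classify_sov(emu_ts(1e-4 * sin(2 * pi * 6 * t), fs), quiet_acc)
  expect_true(all(rem$state == "REM"))
  # sustained acceleration -> WAKE regardless of the LFP
  busy_acc <- emu_ts(c(rep(1e-4, 30), rep(0.05, 30)), 1, units = "g (rms)")
  wake <- classify_sov(emu_ts(1e-4 * sin(2 * pi * 2 * t), fs), busy_acc)
  expect_true(all(wake$state[4:6] == "WAKE"))
  # epochs tile the span contiguously
  expect_equal(wake$t_start_s[-1], wake$t_end_s[-nrow(wake)])
  expect_error(classify_sov(emu_ts(rep(0, 60 * fs), fs),
                            emu_ts(rep(0, 600), 1, t0_s = 500)),
               "misaligned")
})

test_that("SD propagation ordering sorts onsets with label tie-breaks", {
  ev <- data.frame(channel = c("HAL", "HPL"), onset_s = c(104, 100))
  ord <- sd_propagation_order(ev)
  expect_equal(ord$channel, c("HPL", "HAL"))
  expect_equal(ord$delay_s, c(0, 4))
  one <- sd_propagation_order(data.frame(channel = "HPL", onset_s = 50))
  expect_equal(one$delay_s, 0)
  tie <- sd_propagation_order(
    data.frame(channel = c("B", "A"), onset_s = c(10, 10)))
  expect_equal(tie$channel, c("A", "B"))
  expect_equal(tie$delay_s, c(0, 0))
  expect_equal(nrow(sd_propagation_order(
    data.frame(channel = character(0), onset_s = numeric(0)))), 0)
})
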