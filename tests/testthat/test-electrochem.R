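test_that("potentiostat current follows Ohm's law with sign convention", {
  expect_equal(potentiostat_current(0.3, 0.3, 1e4), 0)
  expect_equal(potentiostat_current(0.001, 0, 1e4), 1e-7)  # 1 mV / 10k = 100 nA
  expect_equal(potentiostat_current(0.2, 0.5, 2e3),
               -potentiostat_current(0.5, 0.2, 2e3))
  expect_error(potentiostat_current(1, 0, 0), "positive")
})

test_that("waveform generator reproduces the five stimulus families", {
  # CPA holds the oxygen-sensing bias constant
  cpa <- generate_waveform(waveform_spec("CPA", list(hold_v = -0.65),
                                         duration_s = 2))
  expect_true(all(cpa$values == -0.65))
  # SINE_DC time-mean over whole periods equals the DC offset
  sine <- generate_waveform(waveform_spec(
    "SINE_DC", list(dc_v = 0.3, amp_v = 0.2, freq_hz = 5), duration_s = 2))
  expect_equal(mean(sine$values), 0.3, tolerance = 1e-6)
  # FSCV triangle closed form: 0->1 V at 100 V/s has a 20 ms period and
  # passes 0.5 V at 5 ms
  fscv <- generate_waveform(waveform_spec(
    "FSCV", list(v_min = 0, v_max = 1, scan_rate_v_per_s = 100),
    duration_s = 0.1, update_rate_hz = 1e5))
  expect_equal(fscv$values[round(0.005 * 1e5) + 1], 0.5)
  expect_equal(fscv$values[round(0.020 * 1e5) + 1], fscv$values[1])
  # LTPV rectangular pulses
  ltpv <- generate_waveform(waveform_spec(
    "LTPV", list(base_v = 0, pulse_v = 0.5, pulse_s = 0.1, period_s = 1),
    duration_s = 3, update_rate_hz = 1000))
  expect_equal(ltpv$values[1], 0.5)             # pulse at period start
  expect_equal(ltpv$values[500], 0)             # base between pulses
  expect_equal(mean(ltpv$values == 0.5), 0.1, tolerance = 0.01)
  # DPV staircase ascends by step_v each period with pulses on top
  dpv <- generate_waveform(waveform_spec(
    "DPV", list(start_v = 0, end_v = 0.5, step_v = 0.05, pulse_amp_v = 0.05,
                pulse_s = 0.02, period_s = 0.1),
    duration_s = 1, update_rate_hz = 1e4))
  expect_equal(dpv$values[1], 0)
  expect_equal(dpv$values[round(0.15 * 1e4)], 0.05)   # second tread
  expect_error(waveform_spec("FSCV", list(v_min = 1, v_max = 0,
                                          scan_rate_v_per_s = 10), 1),
               "v_min < v_max")
  expect_error(waveform_spec("CPA", list(), 1), "hold_v")
})

test_that("periodic waveforms repeat exactly", {
  spec <- waveform_spec("SINE_DC", list(dc_v = 0, amp_v = 1, freq_hz = 4),
                        duration_s = 2, update_rate_hz = 1000)
  v <- generate_waveform(spec)$values
  expect_equal(v[1:250], v[251:500], tolerance = 1e-12)
  ltpv <- generate_waveform(waveform_spec(
    "LTPV", list(base_v = -0.1, pulse_v = 0.4, pulse_s = 0.25, period_s = 0.5),
    duration_s = 2, update_rate_hz = 1000))
  expect_equal(ltpv$values[1:500], ltpv$values[501:1000], tolerance = 1e-12)
})

test_that("CPA point value averages the centred 80 s, excluding transients", {
  fs <- 100
  flat <- emu_ts(rep(50, 300 * fs), fs, units = "nA")
  expect_equal(cpa_point_value(flat), 50)
  # large transient in the first 60 s only, flat 30 nA after
  x <- c(500 * exp(-seq_len(60 * fs) / (10 * fs)), rep(0, 240 * fs)) + 30
  expect_equal(cpa_point_value(emu_ts(x, fs)), 30, tolerance = 1e-3)
  # linear ramp a + b t over [0, T] has centred mean a + b T/2
  a <- 10; b <- 0.05; T <- 300
  tt <- (seq_len(T * fs) - 1) / fs
  ramp <- cpa_point_value(emu_ts(a + b * tt, fs))
  expect_equal(ramp, a + b * T / 2, tolerance = 1e-3)
  expect_error(cpa_point_value(emu_ts(rep(1, 50 * fs), fs)), "80")
})

test_that("oxygen dilution follows ideal mass balance", {
  expect_equal(mix_o2_concentration(10, 0), 0.23)
  expect_equal(mix_o2_concentration(5, 5), 0.115)
  # cumulative additions match a brute-force mass balance
  v_air <- 20
  adds <- c(2, 3, 5, 10)
  mass <- 0.23 * v_air; vol <- v_air
  for (k in seq_along(adds)) {
    vol <- vol + adds[k]
    expect_equal(mix_o2_concentration(v_air, sum(adds[1:k])), mass / vol)
  }
  expect_error(mix_o2_concentration(-1, 5), ">= 0")
  expect_error(mix_o2_concentration(0, 0), "positive")
})

test_that("calibration fit recovers lines and honours the fit range", {
  conc <- seq(0.09, 0.23, length.out = 8)
  pts <- data.frame(concentration_mm = conc, current_na = 100 * conc + 5)
  fit <- fit_o2_calibration(pts)
  expect_equal(fit$slope_na_per_mm, 100, tolerance = 1e-9)
  expect_equal(fit$intercept_na, 5, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # closed-form least-squares oracle
  sxx <- sum((conc - mean(conc))^2)
  sxy <- sum((conc - mean(conc)) * (pts$current_na - mean(pts$current_na)))
  expect_equal(fit$slope_na_per_mm, sxy / sxx)
  # an out-of-range outlier changes nothing
  out <- rbind(pts, data.frame(concentration_mm = 0.5, current_na = -999))
  fit2 <- fit_o2_calibration(out)
  expect_equal(fit2$slope_na_per_mm, fit$slope_na_per_mm)
  expect_equal(fit2$n_points, 8)
  expect_error(fit_o2_calibration(pts[1:2, ]), "at least 3")
})

test_that("noisy calibration recovers the slope within a few percent", {
  set.seed(41)
  conc <- seq(0.09, 0.23, length.out = 10)
  slopes <- replicate(50, {
    pts <- data.frame(concentration_mm = conc,
                      current_na = 100 * conc + 5 + rnorm(10, sd = 1))
    fit_o2_calibration(pts)$slope_na_per_mm
  })
  expect_lt(abs(mean(slopes) - 100) / 100, 0.05)
})

test_that("in vivo CPA post-processing decimates after the 1 Hz low-pass", {
  fs <- 1000
  const <- process_invivo_cpa(emu_ts(rep(42, 100 * fs), fs, units = "nA"))
  expect_equal(const$fs_hz, 20)
  expect_equal(const$values, rep(42, 100 * 20), tolerance = 1e-3)
  # length arithmetic: T seconds in -> 20 T samples out
  expect_length(process_invivo_cpa(emu_ts(rep(0, 250 * fs), fs))$values,
                250 * 20)
  # 10 Hz interference is suppressed below 1% of its amplitude
  t <- seq(0, 100 - 1 / fs, by = 1 / fs)
  hum <- process_invivo_cpa(emu_ts(3 * sin(2 * pi * 10 * t), fs))
  expect_lt(max(abs(hum$values[200:1800])), 0.03)
  expect_warning(process_invivo_cpa(emu_ts(rep(1, 4000), 100)), "1000 Hz")
})

test_that("state-conditioned CPA means exclude event-adjacent bouts", {
  hyp <- data.frame(
    t_start_s = seq(0, 540, by = 60),
    t_end_s = seq(60, 600, by = 60),
    state = rep(c("NREM", "REM", "WAKE"), length.out = 10))
  cur <- emu_ts(rep(50, 600 * 20), 20, units = "nA")
  m0 <- state_conditioned_cpa_means(cur, hyp, NULL)
  expect_equal(m0$mean_current, rep(50, 3))
  # REM bouts carry +2 nA
  tt <- ts_times(cur)
  x <- rep(50, length(tt))
  for (b in which(hyp$state == "REM"))
    x[tt >= hyp$t_start_s[b] & tt < hyp$t_end_s[b]] <- 52
  cur2 <- emu_ts(x, 20, units = "nA")
  m2 <- state_conditioned_cpa_means(cur2, hyp, NULL)
  expect_equal(m2$mean_current[m2$state == "REM"] -
                 m2$mean_current[m2$state == "NREM"], 2)
  # a bout straddling an SD is excluded from its state's count
  sd_ev <- data.frame(onset_s = 70, offset_s = 100)
  m3 <- state_conditioned_cpa_means(cur2, hyp, sd_ev, margin_s = 60)
  expect_equal(m3$n_bouts[m3$state == "REM"],
               m2$n_bouts[m2$state == "REM"] - 1)
})
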