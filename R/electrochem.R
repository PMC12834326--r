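# Floating-potentiostat current law, the function generator's five stimulus
# waveforms, constant-potential amperometry (CPA) oxygen calibration, and in
# vivo CPA post-processing. In the floating three-electrode design the
# counter electrode is grounded, the reference floats, and the working-
# electrode current is read from the voltage drop across a sense resistor.

#' Potentiostat current from a sense-resistor voltage drop
#'
#' `i = (v1 - v2) / r`: the current is the potential difference between the
#' two sense points divided by the sense resistance. Positive when point 1
#' is above point 2.
#'
#' @param v1_v,v2_v potentials at the two sense points, volts.
#' @param r_ohm sense resistance in ohm (> 0).
#' @return current in amperes (vectorised).
#' @export
potentiostat_current <- function(v1_v, v2_v, r_ohm) {
  if (any(r_ohm <= 0)) stop("sense resistance must be positive")
  (v1_v - v2_v) / r_ohm
}

#' Stimulus waveform specification
#'
#' One of the function generator's five waveform families:
#' \describe{
#'   \item{CPA}{constant potential; `params$hold_v`.}
#'   \item{FSCV}{fast-scan cyclic voltammetry, symmetric triangle;
#'     `params$v_min`, `params$v_max`, `params$scan_rate_v_per_s`.}
#'   \item{LTPV}{long-term pulse voltammetry, rectangular pulses;
#'     `params$base_v`, `params$pulse_v`, `params$pulse_s`, `params$period_s`.}
#'   \item{DPV}{differential pulse voltammetry, staircase with superimposed
#'     pulses; `params$start_v`, `params$end_v`, `params$step_v`,
#'     `params$pulse_amp_v`, `params$pulse_s`, `params$period_s`.}
#'   \item{SINE_DC}{sinusoid on a DC offset; `params$dc_v`, `params$amp_v`,
#'     `params$freq_hz`.}
#' }
#'
#' @param kind one of `"CPA"`, `"FSCV"`, `"LTPV"`, `"DPV"`, `"SINE_DC"`.
#' @param params named list of kind-specific parameters (above).
#' @param duration_s waveform duration in seconds (> 0).
#' @param update_rate_hz DAC update rate in Hz.
#' @return list of class `waveform_spec`.
#' @export
waveform_spec <- function(kind, params, duration_s, update_rate_hz = 1000) {
  kind <- match.arg(kind, c("CPA", "FSCV", "LTPV", "DPV", "SINE_DC"))
  stopifnot(duration_s > 0, update_rate_hz > 0)
  need <- switch(kind,
    CPA = "hold_v",
    FSCV = c("v_min", "v_max", "scan_rate_v_per_s"),
    LTPV = c("base_v", "pulse_v", "pulse_s", "period_s"),
    DPV = c("start_v", "end_v", "step_v", "pulse_amp_v", "pulse_s",
            "period_s"),
    SINE_DC = c("dc_v", "amp_v", "freq_hz"))
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop("waveform '", kind, "' missing parameter(s): ",
         paste(missing, collapse = ", "))
  if (kind == "FSCV") {
    if (params$v_min >= params$v_max) stop("FSCV requires v_min < v_max")
    if (params$scan_rate_v_per_s <= 0) stop("FSCV scan rate must be positive")
  }
  if (kind %in% c("LTPV", "DPV") && params$pulse_s >= params$period_s)
    stop(kind, " requires pulse_s < period_s")
  if (kind == "SINE_DC" && params$freq_hz <= 0)
    stop("SINE_DC requires freq_hz > 0")
  structure(list(kind = kind, params = params[need],
                 duration_s = as.numeric(duration_s),
                 update_rate_hz = as.numeric(update_rate_hz)),
            class = "waveform_spec")
}

#' Generate the control-potential waveform of a spec
#'
#' Samples the control potential at the DAC update rate for the spec'd
#' duration. Samples are taken at t = 0, 1/rate, 2/rate, ...
#'
#' @param spec a [waveform_spec()].
#' @return [emu_ts()] of the control potential in volts.
#' @export
generate_waveform <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  fs <- spec$update_rate_hz
  t <- seq(0, spec$duration_s - 1 / fs, by = 1 / fs)
  p <- spec$params
  v <- switch(spec$kind,
    CPA = rep(p$hold_v, length(t)),
    FSCV = {
      span <- p$v_max - p$v_min
      period <- 2 * span / p$scan_rate_v_per_s
      ph <- (t %% period) / period            # 0..1
      p$v_min + span * (1 - abs(2 * ph - 1))  # triangle starting at v_min
    },
    LTPV = ifelse(t %% p$period_s < p$pulse_s, p$pulse_v, p$base_v),
    DPV = {
      step_idx <- floor(t / p$period_s)
      base <- p$start_v + pmin(step_idx * p$step_v,
                               rep(p$end_v - p$start_v, length(t)))
      in_pulse <- (t %% p$period_s) >= (p$period_s - p$pulse_s)
      base + ifelse(in_pulse, p$pulse_amp_v, 0)
    },
    SINE_DC = p$dc_v + p$amp_v * sin(2 * pi * p$freq_hz * t))
  emu_ts(v, fs_hz = fs, units = "V", label = paste0("Vc_", spec$kind))
}

#' CPA point value: mean of the middle 80 s
#'
#' The reported value of a ~5 min CPA calibration recording is the mean over
#' the centred 80 s window `[T/2 - 40 s, T/2 + 40 s]`, excluding the
#' transient response to the dilution step at the start.
#'
#' @param current an [emu_ts()] of electrode current spanning at least 80 s.
#' @param window_s summary window length in seconds (default 80).
#' @return mean current over the centred window (same units as input).
#' @export
cpa_point_value <- function(current, window_s = 80) {
  stopifnot(inherits(current, "emu_ts"))
  dur <- ts_duration(current)
  if (dur < window_s)
    stop("trace of ", dur, " s is shorter than the ", window_s, " s window")
  fs <- current$fs_hz
  mid <- dur / 2
  i0 <- max(1L, as.integer(floor((mid - window_s / 2) * fs)) + 1L)
  i1 <- min(length(current$values),
            as.integer(ceiling((mid + window_s / 2) * fs)))
  mean(current$values[i0:i1])
}

#' Oxygen concentration of an air/N2-saturated mixture
#'
#' Ideal dilution: the N2-saturated stock carries no oxygen, so
#' `c = c_air_sat * v_air / (v_air + v_n2)`.
#'
#' @param v_air_ml volume of air-saturated solution (>= 0).
#' @param v_n2_ml volume of N2-saturated solution (>= 0).
#' @param c_air_sat_mm oxygen concentration of the air-saturated stock in
#'   mM/L (default 0.23, the arterial anchor at the calibration temperature).
#' @return oxygen concentration in mM/L.
#' @export
mix_o2_concentration <- function(v_air_ml, v_n2_ml, c_air_sat_mm = 0.23) {
  if (any(v_air_ml < 0) || any(v_n2_ml < 0)) stop("volumes must be >= 0")
  if (any(v_air_ml + v_n2_ml == 0)) stop("total volume must be positive")
  c_air_sat_mm * v_air_ml / (v_air_ml + v_n2_ml)
}

#' Fit the oxygen-sensing electrode calibration line
#'
#' Ordinary least squares of current on concentration, restricted to points
#' inside the physiological range (default 0.09-0.23 mM/L, tissue to
#' arterial oxygen concentration).
#'
#' @param points data.frame with `concentration_mm` and `current_na`.
#' @param range two-element concentration range in mM/L kept for the fit.
#' @return list of class `o2_calibration`: `slope_na_per_mm`,
#'   `intercept_na`, `r2`, `fit_range_mm`, `n_points`.
#' @export
fit_o2_calibration <- function(points, range = c(0.09, 0.23)) {
  stopifnot(all(c("concentration_mm", "current_na") %in% names(points)))
  keep <- points$concentration_mm >= range[1] &
          points$concentration_mm <= range[2]
  pts <- points[keep, , drop = FALSE]
  if (nrow(pts) < 3)
    stop("need at least 3 calibration points inside [", range[1], ", ",
         range[2], "] mM/L; got ", nrow(pts))
  fit <- stats::lm(current_na ~ concentration_mm, data = pts)
  sst <- sum((pts$current_na - mean(pts$current_na))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(
    slope_na_per_mm = unname(stats::coef(fit)[2]),
    intercept_na = unname(stats::coef(fit)[1]),
    r2 = r2,
    fit_range_mm = range,
    n_points = nrow(pts)),
    class = "o2_calibration")
}

#' Post-process an in vivo CPA current trace
#'
#' Low-pass filters at `cutoff_hz` (default 1 Hz) and then decimates by
#' simple stride to `out_fs_hz` (default 20 Hz), the in vivo convention for
#' 1 kHz recordings. The anti-alias cutoff sits far below the output Nyquist,
#' so stride decimation is exact.
#'
#' @param current an [emu_ts()] of electrode current, nominally at 1000 Hz
#'   (a warning is raised otherwise; the decimation factor is rescaled).
#' @param cutoff_hz low-pass cutoff in Hz.
#' @param out_fs_hz output sampling rate in Hz.
#' @return decimated [emu_ts()] at `out_fs_hz`.
#' @export
process_invivo_cpa <- function(current, cutoff_hz = 1, out_fs_hz = 20) {
  stopifnot(inherits(current, "emu_ts"))
  if (current$fs_hz != 1000)
    warning("expected 1000 Hz input; decimating from ", current$fs_hz,
            " Hz instead")
  stride <- current$fs_hz / out_fs_hz
  if (stride != round(stride))
    stop("fs/out_fs must be an integer decimation factor")
  lp <- lowpass(current, cutoff_hz)
  out <- lp
  out$values <- lp$values[seq(1, length(lp$values), by = stride)]
  out$fs_hz <- out_fs_hz
  out
}

#' State-conditioned CPA means over clean vigilance bouts
#'
#' Collapses a hypnogram into bouts (maximal runs of one state), excludes
#' bouts that start or end within `margin_s` of any exclusion event (seizure
#' or SD), and returns the mean CPA current and bout count per state.
#'
#' @param cpa an [emu_ts()] of (processed) CPA current.
#' @param hypnogram a `hypnogram` data.frame from [classify_sov()].
#' @param exclusion_events data.frame with `onset_s`, `offset_s` (zero rows
#'   or `NULL` for none).
#' @param margin_s exclusion margin around events in seconds (default 60).
#' @return data.frame with `state`, `mean_current`, `n_bouts`; states with
#'   no clean bouts are absent.
#' @export
state_conditioned_cpa_means <- function(cpa, hypnogram,
                                        exclusion_events = NULL,
                                        margin_s = 60) {
  stopifnot(inherits(cpa, "emu_ts"))
  h <- hypnogram[hypnogram$state != "UNSCORED", , drop = FALSE]
  if (nrow(h) == 0)
    return(data.frame(state = character(0), mean_current = numeric(0),
                      n_bouts = integer(0)))
  runs <- rle(h$state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  bouts <- data.frame(state = runs$values,
                      t_start_s = h$t_start_s[starts],
                      t_end_s = h$t_end_s[ends])
  if (!is.null(exclusion_events) && nrow(exclusion_events) > 0) {
    bad <- vapply(seq_len(nrow(bouts)), function(b) {
      any(bouts$t_start_s[b] < exclusion_events$offset_s + margin_s &
          bouts$t_end_s[b] > exclusion_events$onset_s - margin_s)
    }, logical(1))
    bouts <- bouts[!bad, , drop = FALSE]
  }
  if (nrow(bouts) == 0)
    return(data.frame(state = character(0), mean_current = numeric(0),
                      n_bouts = integer(0)))
  tt <- ts_times(cpa)
  means <- tapply(seq_len(nrow(bouts)), bouts$state, function(rows) {
    sel <- rep(FALSE, length(tt))
    for (b in rows)
      sel <- sel | (tt >= bouts$t_start_s[b] & tt < bouts$t_end_s[b])
    mean(cpa$values[sel])
  })
  counts <- table(bouts$state)
  data.frame(state = names(means),
             mean_current = as.numeric(means),
             n_bouts = as.integer(counts[names(means)]),
             row.names = NULL)
}
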