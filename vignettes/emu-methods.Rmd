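---
title: "Methods: DC-coupled multimodal epilepsy monitoring analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DC-coupled multimodal epilepsy monitoring analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimon)
```

## Scope

`epimon` implements the offline computational stack of a DC-sensitive
rodent epilepsy monitoring unit (EMU): the rig's binary telemetry dialect,
the signal-conditioning conventions, four event detectors (spreading
depolarization, seizure counting, cardiac R peaks, vigilance state), the
electrochemical-interface calculations for constant-potential amperometry
(CPA) oxygen sensing, a video/electrophysiology synchronization check, and
a seeded multimodal simulator that provides ground truth for all of the
above. This vignette records the models, parameter choices and numerical
decisions, in the order a user meets them.

## Telemetry format

An hourly file is a 4096-byte header followed by 63-byte packets:
a 3-byte wrapping counter, a 3-byte status word and 8 signed 24-bit channel
codes per analog front end (two front ends, 16 biopotential channels), and
3 signed 16-bit acceleration codes. Channel codes are big-endian two's
complement (the AFE's native output order), acceleration codes
little-endian (the accelerometer's native order) — these orders are stated
so that independent readers interoperate. The header content is specified
only as "configuration details" of a fixed 4096-byte size, so the dialect
here is self-describing UTF-8 `key=value` lines, zero-padded, with a magic
first line; it is inspectable with any pager and size-exact by
construction. Status words are carried opaquely: their flag semantics
belong to the converter datasheet, and nothing downstream reads them.

Physical units: `volts = code * (vref/gain) / 2^23`, giving the rig's
±4.5 V dynamic range at gain 1, vref 4.5 V; acceleration
`g = code * full_scale / 2^15`. Export saturates (never wraps) codes
beyond full scale and reports the count; a round trip through the format
is exact to 1/2 LSB per sample. Trailing partial packets — the signature
of power loss — are surfaced as a warning with the byte count, never
silently dropped. File rotation occurs on the hour boundary of *elapsed
samples* (`fs * 3600` packets), not wall clock, so the size law
`4096 + 63N` stays exact.

## Signal conditioning

Field potentials use a 0.5–125 Hz band-pass convention; acceleration power
and spectrograms use 1 s windows after a 2–125 Hz band-pass; spectra are
Welch averages over 2048-sample Hann windows (50% overlap — overlap and
taper are unstated upstream, so the field defaults are fixed here and
stated); in vivo CPA current is low-passed at 1 Hz and decimated from
1 kHz to 20 Hz by stride (the anti-alias cutoff sits 10x below the output
Nyquist, so stride decimation is exact).

All filters are 4th-order Butterworth applied forward–backward: zero phase
preserves the event onset times every detector depends on. Two numerical
decisions matter at these cutoffs:

* **Second-order sections.** 0.5 Hz on 1 kHz data is a normalized cutoff
  of 10^-3; the expanded-polynomial recursion loses ~7 digits there (and a
  direct band-pass design produces NaNs outright). Filters are therefore
  designed as bilinear-transformed biquad cascades, each section
  gain-normalized exactly at its reference frequency. Linearity holds to
  ~10^-12 relative; a band-pass is the cascade of its high-pass and
  low-pass halves with the edges as −3 dB points.
* **Edge handling.** Forward–backward filtering from zero state leaves
  seconds-long edge transients at low cutoffs. Signals are odd-reflected
  about their endpoints (pad length: three time constants of the slowest
  edge) and shifted to start at zero; the offset is restored through the
  cascade's squared DC gain. Constant traces pass through the low-pass
  bit-exactly.

"Mean square root power" of acceleration is read as windowed RMS of the
band-filtered three-axis vector magnitude; this is the only place that
wording is interpreted, and it is not generalized elsewhere. The 125 Hz
upper edge presumes the rig's 1 kHz rate and is clamped below Nyquist for
slower inputs.

## Spreading depolarization detector

SDs are detected on the 0.5 Hz low-passed, DC-coupled trace. Onset: the
first sample whose drop relative to the value 3 s earlier (an exact sample
shift of `round(3 fs)`) reaches 7.5 mV. Offset: the first later sample at
or above the onset potential + 2 mV. The detector re-arms after each
offset; events still open at end of trace are emitted with the offset at
trace end and flagged `truncated` rather than dropped. Threshold
comparisons are inclusive crossings with a 1 nV guard, so boundary
decisions are invariant to filter round-off; 1 nV is four orders below any
physical signal here.

Two consequences of the rule are worth stating because they are easy to
misread as bugs:

* A ramp slower than 2.5 mV/s can never fire the detector: the 3 s
  look-back saturates at 3x the slope. An SD whose DC shift develops over
  20 s at 35 mV total is (correctly) invisible to this rule.
* The onset potential sits ~7.5 mV below baseline by construction, so the
  reported `amplitude_v` is referenced to the pre-onset look-back value
  (baseline-to-trough), matching how SD amplitude is quoted in the field;
  `onset_potential_v` is still reported and still anchors the offset rule.

The detector is derivation-agnostic: it makes no assumption about
referential vs bipolar montages.

## Seizure detection and counting

Candidate generation is a band-power threshold detector — the simplest
mechanism consistent with the described signature (sentinel spike, then a
9–16 Hz spike burst, then a sharp power decrease): per channel, 9–16 Hz
band power in 1 s windows; a candidate opens after 2 consecutive windows
above 5x a rolling 5-minute median baseline and closes after 2 below;
overlapping candidates merge across channels. All parameters are exposed.
An optional sentinel-spike gate exists but defaults off: the upstream
description gives it no quantitative definition. Known limitation: on full
multimodal sessions the rolling median mixes vigilance states near
transitions, which can produce brief false candidates; the counting stage
absorbs most of these, and the detector's contracts are stated for
stationary backgrounds.

Counting applies the rule exactly: candidates closer than 10 min merge
into one event (merge-then-filter — clusters are counted as grouped
episodes, not by dropping later members), and events not longer than 10 s
are discarded. The suite checks this against a brute-force rule oracle on
1000 random candidate lists.

## Cardiac R peaks and vigilance state

R peaks: 15–125 Hz band-pass, polarity auto-detected from the skewness of
the filtered trace, local maxima above an adaptive threshold (half the
rolling 99.9th percentile over 10 s blocks, floored at 5 MADs), 60 ms
refractory keeping the larger peak (supports rates to 1000 bpm). RR
intervals are first differences of peak times; their sum telescopes to
last minus first peak exactly.

Vigilance (10 s epochs; epoch length is unstated upstream and fixed here):
WAKE when median windowed acceleration power exceeds 3x the session's 20th
percentile; else REM when the theta (4–7 Hz) to delta (0.5–4 Hz) power
ratio exceeds 1.5 *and* the 0.5–12 Hz spectral argmax lies in theta; else
NREM when the argmax lies in delta; else UNSCORED. Epochs tile the scored
span contiguously. These thresholds are scoring heuristics, not a
human-grade stager, and all three are configurable.

## Electrochemistry

The floating potentiostat grounds the counter electrode, lets the
reference float, and reads the working-electrode current from the voltage
drop across a sense resistor: `i = (v1 - v2)/R`, positive when point 1 is
above point 2. The function generator reproduces the five stimulus
families (CPA hold, FSCV triangle, long-term pulse, differential pulse,
sine-on-DC); DPV current-sampling conventions are options since only the
waveform is specified upstream.

Calibration: each dilution point is the mean of the middle 80 s of a
~5 min recording (transients from the N2-saturated addition excluded);
concentrations follow ideal dilution from an air-saturated stock
(default 0.23 mM/L at the calibration temperature — the arterial anchor —
and user-overridable, since temperature dependence is not specified
further); the line is ordinary least squares restricted to the
physiological 0.09–0.23 mM/L range. State-conditioned in vivo means
exclude vigilance bouts that start or end within 60 s of any seizure or SD
event. The CPA measure cannot decouple oxygen concentration from the
diffusion coefficient; nothing here attempts to.

## Synchronization check

Video actigraphy is the windowed mean of |ΔI| between consecutive frames
(per-pixel first for frame stacks, frame-mean otherwise — both modes
exist because the reduction order is ambiguous upstream); accelerometer
actigraphy is the windowed RMS described above. Both series are high-pass
filtered at 10 mHz (first-order, forward–backward) on their 1 s grid,
mean-removed, and cross-correlated with Pearson-style normalization over
±120 s, making the peak value a confidence score. Positive lag means the
second series lags the first. The 1 s grid bounds resolution at ±1 window,
which is exactly the acceptance band a synchronized rig is held to.

## The simulator and what passing means

The simulator is a test harness, not a biophysical model. Per state it
generates: NREM as 0.5–4 Hz band noise over a broadband floor, REM as
6 Hz theta with light fast noise, WAKE as broadband noise plus movement;
seizures as a sentinel spike, a 12 Hz burst envelope and a −5 mV DC
plateau; SDs as a raised-cosine fall (5 s), plateau, and exponential
recovery (tau 8 s) of configured amplitude (floor 20 mV) and duration
(30–60 s) with per-channel delays; ECG as an impulse train convolved with
an 16 ms raised-cosine QRS kernel at 6 Hz (rat-typical 360 bpm); CPA as
state-dependent means (defaults 52/50/51 nA for REM/NREM/WAKE, encoding
the REM > NREM tissue-oxygen ordering) with AR(1) noise; video intensity
as a random walk whose step size follows the same movement envelope as the
accelerometer, optionally delayed by a planted clock skew. Every stream
draws from its own substream of the master seed, so adding a modality
never perturbs the others; identical seeds give bit-identical sessions.

The 5 s SD fall time is a generator property worth naming: it is fast
enough that the 7.5 mV/3 s rule localizes onset within 3 s even at the
20 mV amplitude floor, and it is inside the physiologic range for SD
DC-shift development. Real data differ from all of this in ways the suite
cannot certify: colored and nonstationary noise, movement and chest-muscle
artifact, electrode drift, mixed cortical/hippocampal fields under a
common reference. Passing tests therefore demonstrate that the rules are
implemented exactly and recover planted structure under clean conditions —
not field performance on in vivo recordings.

Problem sizes in the suite were chosen for single-CPU runs: 30-minute
single-channel sessions for synchronization, 8-minute sessions for SD
recovery (20 seeded scenarios), 2-minute ECG segments, and 1000-list
counting-rule sweeps; the full suite runs in a few minutes.

## Known limitations

* The seizure candidate detector is a threshold heuristic; it neither
  classifies semiology nor rejects artifact.
* The SOV scorer is three-state with fixed spectral bands; no
  transition-probability smoothing.
* EDF+ export is not provided (CSV only); no reader for other rigs'
  dialects.
* Status-word flags are not interpreted.
* Cardiac analysis presumes relative stillness; the simulator does not
  model chest-muscle contamination at all.
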