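---
title: "Methods: steering, physiology and the correlation study in drivesense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steering, physiology and the correlation study in drivesense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivesense)
```

# The measurement model

A gyroscope sits on the steering-wheel rotation axis and reports the
signed angular speed ω (degrees/second) of the wheel, typically at
10.2 Hz. Positive ω is counter-clockwise as seen by the driver — the
convention is arbitrary but fixed, and every feature below is either
sign-symmetric or explicitly signed. Sample *i* (1-based) of a trace with
start time *t0* is taken at *t0 + (i−1)/Fs*; all times are seconds from
session start, which matches the one-record-per-second vehicle telemetry
and avoids epoch ambiguity.

The wheel angle is recovered by rectangular integration,
*position[i] = position[i−1] + ω[i]/Fs*, and a complete-turn counter
increments whenever the running |position| exceeds 360°, after which the
position is rebased by subtracting a signed 360° so continued rotation in
either direction can register further turns (the alternative — clamping or
resetting to zero — would silently miscount multi-turn manoeuvres).

# Steering features and their conventions

Several small ambiguities had to be resolved; each resolution is a package
convention, stated here rather than hidden in code:

* **Interval histogram.** The five intervals (≥10, 7.5–10, 5–7.5, 2.5–5,
  <2.5) classify the *absolute* angular speed in °/s. Left and right
  turning are symmetric, so a signed classification would split each
  behavioural regime across mirrored bins. Boundaries are half-open,
  closed at the lower edge. Per-bin mean and SD are computed on |ω|;
  empty and single-sample bins report SD 0.
* **Zero crossings.** A crossing is an adjacent pair of samples with
  opposite *effective* sign, where a zero-valued sample inherits the most
  recent nonzero sign. Touching zero and returning is therefore not a
  crossing, and a leading run of zeros is signless. The event index is the
  later sample of the pair.
* **Running maximum.** The maximum of |ω| is tracked from the first
  sample; an update event requires strictly exceeding the previous
  maximum, so the first sample is always an update and constant traces
  have exactly one.
* **Windowed statistics.** EMG/GSR streams, ω itself and the per-sample
  turn counter are summarised in non-overlapping 20-sample sets (mean and
  sample SD, n−1 denominator; a single observation has SD 0 by
  convention). An incomplete tail set is excluded from the windowed series
  but retained in the cumulative statistics. At 10.2 Hz a 20-sample window
  is roughly two seconds of driving.
* **Low-attention rule.** Traces are cut into consecutive periods of
  `floor(period_s · Fs)` samples — 51 at the 10.2 Hz/5 s defaults — and a
  period is flagged when the union of the period and its predecessor
  contains **no** zero crossing **and** at least one running-maximum
  update. The "this period or the previous one" scope is applied to *both*
  conjuncts, which is the stricter of the two available readings (a flag
  is harder to raise); the first period is evaluated over itself alone.
  The quantity entering the rule is the absolute angular *speed*,
  consistent with the running-maximum feature it reuses. Note
  `floor(5 × 10.2)` is 50 in floating point; the package computes period
  lengths with a 1e-9 slack so the 51-sample geometry is exact.
* **Turn-count windows.** The 20-value summaries of the turn counter
  operate on the counter's per-sample *value* (not its increments): the
  displayed quantity is "how many turns so far", so its windowed mean
  tracks the counter level.

Every feature exists in batch form and in a streaming tracker that
consumes one sample at a time (Welford accumulators for global and per-bin
moments, explicit window buffers, incremental crossing/maximum/turn
state). The test suite asserts batch/streaming identity to floating-point
accumulation error on randomised traces.

# ECG, HRV and channel summaries

The R-peak detector is a deliberately dependency-free time-domain scheme:
subtract a centred moving average (0.6 s window) to remove baseline wander,
threshold at half of the local signal maximum over the current and previous
3-s block, keep local maxima above threshold, and enforce a 0.2-s
refractory period in which the larger candidate wins. It is deterministic
and, on the synthetic ECG below, recovers clean peaks exactly and ≥95 % of
peaks within ±20 ms at an amplitude SNR of 10. It is *not* a clinical
delineator: Q/S/T morphology, ectopy and artefact handling are out of
scope.

"HRV" is summarised as the mean R-R interval, with the sample SD of the
R-R sequence alongside and mean heart rate 60/mean-RR. The choice of mean
R-R (rather than SDNN or a frequency-domain index) is a package decision —
the quantity the rest of the pipeline consumes is the per-session mean
level, and the SD is reported for anyone who prefers a dispersion measure.

EMG summaries operate on raw signed millivolt samples by default;
`rectify = TRUE` switches to |EMG| where an amplitude reading is wanted
(the rested/tired comparison in the tests uses rectified means, since a
zero-mean noise channel has a signed mean of ~0 in both states).

# The synthetic-session generator

No public dataset accompanies this problem, so the generator is
first-class, tested code; its defaults *are* the study conditions.

**Alert steering** is zero-mean Gaussian micro-correction noise (SD
2 °/s) plus Poisson-timed correction pulses (2 events/s, half-sine,
0.3 s, amplitude 3–8 °/s), scaled per driver by a `steering_scale`
vigour factor. This yields ~4 zero crossings per second at 10.2 Hz.

**Drowsy steering** is a near-still wheel: a piecewise-constant creep of
0.4–1.0 °/s whose direction persists for ~10 s stretches, plus smooth
AR(1) noise (stationary SD 0.2 °/s, φ = 0.9), interrupted by rare
corrective spikes (0.3 events/s, half-sine, 0.5 s, amplitude ~30 °/s)
that *continue the creep direction* — a hard turn from near-zero speed
without a sign change. The creep magnitude and same-sign spikes were
design-calibrated so the regime actually exhibits the signature the
low-attention rule targets: long crossing-free windows that still contain
running-maximum updates. (With sign-random spikes, half of all spikes
create a crossing that vetoes the flag, and the rule fires almost never —
the rule's two conjuncts are then nearly mutually exclusive.) A useful
consequence of the running-maximum definition is that low-attention flags
are intrinsically rare late in a session: among k spikes only ~ln k set
new records, so counts per session are small single digits, as one would
expect of a measure of discrete lapses.

**Physiology.** ECG is a raised-cosine R wave (1 mV, 50 ms) plus a small
T bump at each programmed beat, with Gaussian R-R jitter (SD 50 ms rested,
25 ms tired) around 60/base-HR, at 128 Hz; the programmed peak times are
returned so recovery tests can close the loop. EMG is zero-mean noise
(0.15 mV) multiplied by `emg_gain_tired` (default 1.8) when tired; GSR is
a slow random walk around 200 kOhm shifted by `gsr_shift_tired` (default
50 kOhm) when tired. The three channels draw from sub-seeds derived only
from the profile seed, so a rested/tired pair with the same seed shares
noise and differs exactly by the programmed state effects.

**Vehicle and offences.** Speed is AR(1) around the regime mean (40 km/h
urban, 90 interurban), rpm and fuel are noisy affine functions of speed,
position integrates speed along a wandering heading; offences are Poisson
in time with kinds drawn from the closed 18-label vocabulary. The vehicle
model is deliberately crude — the package tests analytics, not vehicle
physics.

**Cohorts.** `simulate_cohort()` draws latent sleepiness z per driver and
two further factors correlated at the design's ρ. The
`"sdw_leaving_road"` plant loads steering vigour on one factor and the
leaving-the-road rate on the other, keeping every driver alert so the
planted signal is not confounded by regime switching; the
`"sss_offences"` plant loads the Stanford score and the total offence
rate, and ties the drowsy probability to z through a steep logistic
(plogis(−0.5 + 4z)) so sleepiness visibly drives the steering regime.
Questionnaire scores are discretised linear loadings clamped to their
scales (KSS 1–9, SSS 1–7, ESS 0–24). Sessions default to 600 s, a typical
simulator route length; rates and loadings were chosen once so that at
n = 100 drivers the Poisson noise on offence rates attenuates a planted
ρ = 0.6 to an observed r around 0.55 — recovery is asserted within ±0.2,
not to the nominal value, precisely because rate estimation noise and
score discretisation attenuate correlations in any finite study.

**What the generator does not emulate** — and therefore what passing
tests do and do not show: real steering spectra and road curvature, ECG
morphology beyond the R/T caricature, electrode artefacts, learning or
fatigue drift within a session, and any dependence structure between
offence kinds. Recovery results validate the *pipeline's* correctness,
not field performance on human data.

# The correlation study

Offence counts are divided by session duration before any comparison,
since route completion times differ. For each scenario class (urban and
interurban analysed separately, both gear shifts pooled) every pair of
analysis variable (mean ω, SD ω, mean speed, rpm, fuel) and per-kind
offence rate is screened and tested:

* **Normality gate.** Each variable is screened with the Shapiro-Wilk
  test (via `stats::shapiro.test`); a pair is tested when *at least one*
  side is declared normal (p > 0.05). Requiring only one normal margin is
  a deliberately lenient, documented rule — kept as stated rather than
  silently "fixed" to a both-margins or rank-based alternative. The
  screen's α is a separate parameter from the significance α so that
  changing the latter never changes which pairs are tested.
* **Pearson r and p.** r = σ_XY/(σ_X σ_Y) computed from the defining
  formula; the p-value uses the two-sided t-transform on n−2 degrees of
  freedom (the method is not otherwise pinned down; `stats::cor.test`
  serves as an independent cross-check in the tests, never as the
  implementation).
* **No multiplicity correction by default**, matching an uncorrected
  many-offence-type screen; `adjust = "holm"` is available. On null
  cohorts the per-pair false-positive rate sits at the nominal 5 % within
  Monte-Carlo error.

Aggregation to the study table is exact: counts are summed and divided by
total duration, means are duration-weighted, and the pooled SD of ω is
combined from per-session moments (equal to the SD of the concatenated
samples). The low-attention study aggregates per-driver counts across all
sessions and correlates them, and the total offence count, against KSS,
SSS, ESS, age, licence years and racing-game experience; an all-alert
cohort yields a constant outcome, reported as untested rather than an
error.

# The synchronisation protocol

The server listens on TCP (default 8080; ports below 1024 rejected,
mirroring mobile-API restrictions) and drives a strict state machine:
idle → recording (`start`) ⇄ paused (`pause`/`resume`) → stopped
(`stopall`, the fixed wire token). Paused time is excluded from the
recorded duration. After `stopall` the session files are materialised via
a pluggable data source and sent with explicit framing — a header line
`file <name> <bytes> <md5>` followed by exactly that many raw bytes — and
the client verifies length and checksum before accepting. Length-prefix
framing was chosen because line-oriented transfer corrupts binary content
and leaves file boundaries ambiguous. Base R sockets expose no peer
address, so the "allowed peer" check rides on a mandatory
`connect <peer>` handshake token; a mismatch is refused before any state
change. Commands in the wrong state receive an `error` reply and change
nothing, so recording can never occur outside a start/stopall span.

# Numerical choices and problem sizes

Sample SDs use the n−1 denominator everywhere, with the single-observation
SD defined as 0. Period and trace lengths computed from `seconds × Fs` use
a 1e-9 slack before `floor` (10.2 is not representable in binary).
Session CSVs write numbers with `%.15g`, so a write/read cycle preserves
values far below the 1e-9 round-trip contract, and files are written in
binary mode with sorted trace order for byte-deterministic output.

The bundled validation sizes were chosen to exercise each claim at a
scale where its Monte-Carlo error is informative while keeping a desk run
short: 1000 random traces for the oracle-equivalence checks, 50 + 50
one-minute traces for regime separation, and 200 planted plus 200 null
cohorts of 100 drivers × 600 s for correlation recovery. The full
acceptance computation takes a few minutes on one CPU.

# Known limitations

Single-axis steering only (the z-axis gyroscope); no frequency-domain or
nonlinear HRV; the normality gate is lenient by design; correlation is
linear — planted monotone-but-nonlinear effects would be attenuated; the
protocol serves one session per connection and does not attempt NAT
traversal or discovery; and all validation is against synthetic data, so
thresholds such as the drowsy spike amplitude should be re-estimated
before any use on human recordings.
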