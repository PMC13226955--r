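---
title: "Closed-loop REM deprivation in silico: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop REM deprivation in silico: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remloop)
```

remloop re-creates, entirely in software, an automated closed-loop REM sleep
deprivation system for mice: real-time EEG spectral analysis, per-animal
threshold classification, and TTL-triggered mechanical stimulation, run
against a simulated animal. This vignette explains the models behind each
stage, the tunable parameters and their defaults, and the design decisions
that were genuinely open — so that results produced with the package can be
interpreted (and criticized) precisely.

## The detection pipeline

The simulated acquisition front end matches a 16-bit, ±5 mV, 1 kHz
single-channel EEG recording band-limited to 0.5–500 Hz. A 5 s sliding
window (5000 samples) advances every 100 ms — a 98 % overlap — and at each
step the window is Hanning-tapered, zero-padded to 10,000 points (0.1 Hz
bins), and reduced to two band-power ratios by Riemann summation of the
one-sided periodogram:

- $R_{\theta/\delta} = P[4,8)/P[0.5,4)$ — theta against delta power,
  separating REM (theta-dominant) from NREM (delta-dominant);
- $R_{HF} = P[90,200)/P[0.5,500]$ — the high-frequency fraction of total
  power, separating wakefulness (and movement artifact) from sleep.

Band edges are closed on the left and open on the right so that the shared
4 Hz edge between delta and theta is never double-counted; the terminal
Nyquist bin is included in the total band, and the DC bin is excluded from
every band (the front end is high-passed at 0.5 Hz). The periodogram uses
one-sided density scaling with the Hanning power correction. Both features
are ratios, so any consistent scaling gives identical results; density
scaling was fixed so that `band_power()` sums are interpretable in mV² on
their own. No detrending beyond the taper is applied, matching a pipeline
that does no online digital filtering.

Classification is a fixed partition of the feature plane: Wake whenever
$R_{HF} \ge \tau_{HF}$, otherwise REM if
$R_{\theta/\delta} \ge \tau_{\theta/\delta}$, otherwise NREM. Giving the
high-frequency test precedence is the only reading that makes the partition
total, and it doubles as artifact rejection: platform motion raises
high-frequency power, so shaking epochs read as Wake, never as REM. Windows
with degenerate features (zero denominators, or the first 5 s of a session
while the buffer fills) are emitted as Wake with an `undefined`/warmup flag
— the fail-safe direction, since Wake never triggers stimulation.

Per-animal thresholds come from a labeled baseline:
$\tau_{\theta/\delta} = \text{mean}(R_{\theta/\delta}^{REM}) -
\text{sd}(R_{\theta/\delta}^{REM})$ and
$\tau_{HF} = \text{mean}(R_{HF}^{NREM}) + \text{sd}(R_{HF}^{NREM})$.
The SD is the sample standard deviation ($n-1$): the estimator of choice at
small epoch counts, and the difference from the population form vanishes at
calibration-scale $n$. Calibration refuses to run with fewer than two REM
or NREM epochs, and `validate_thresholds()` gates closed-loop entry on
per-state recall over a held-out labeled session. The gate levels
(REM ≥ 0.8, Wake ≥ 0.7, NREM ≥ 0.8) are configuration, not constants of the
method; they were chosen to sit safely below the recall the pipeline
achieves on well-separated data while still catching swapped or corrupted
thresholds.

For offline scoring, the 10 Hz decision stream is aggregated into 2.5 s
epochs of 25 decisions by majority vote. Ties are broken by the fixed
priority REM > NREM > Wake: in a deprivation device the costly error is
missing REM, so ambiguous epochs lean toward the target state. The
tie-break is exercised exhaustively over all three-part compositions of 25
in the test suite.

## The virtual mouse

The synthetic-data generator is the package's replacement for an implanted
animal, and its defaults *are* the study conditions for every simulated
experiment in the tests and the acceptance script.

**Sleep dynamics** are a three-state Markov chain at the 2.5 s epoch scale.
The default transition matrix is solved from a target stationary occupancy
of exactly (REM 7 %, Wake 45 %, NREM 48 %) — matching a baseline in which
REM occupies about 7 % of the day — together with a mean REM bout of 75 s,
REM entered from NREM and exited to Wake, and NREM bouts of roughly
2.5 min. Dwell-time distributions are not reported for the real animals;
these bout lengths are the package's own modelling choice, picked at the
middle of the range commonly reported for adult mice. Occupancy of
generated hypnograms converges to the chain's stationary distribution, a
property checked against an independent power-iteration oracle.

**EEG synthesis** is deliberately minimal: per state, a sum of narrowband
oscillators (sinusoids whose frequency is redrawn within the component
bandwidth at each bout, phase-continuous within a bout) over a background
of an AR(1) (Lorentzian) low-frequency process plus a white broadband
floor. An FFT-shaped $1/f$ background was considered and rejected because
the control loop needs the generator to stream 100 ms blocks with exact
state continuity; the AR(1) recursion carries its state across blocks,
while block-wise FFT shaping cannot. The default amplitudes put the mean
features near physiological values ($R_{\theta/\delta}$ ≈ 7 in REM versus
≈ 0.05 in NREM; $R_{HF}$ ≈ 0.15 in Wake versus ≈ 0.003 in sleep) with
enough within-state spread that thresholds, not luck, do the separating.
EMG is white noise with per-state RMS (Wake 0.15 mV > NREM 0.03 ≥ REM
0.01), used for the feature-space export only — classification is EEG-only.
Samples are clipped to the ±5 mV ADC range and clipping events are counted
on the trace. A cohort constructor jitters all amplitudes log-normally
(±15 %) per animal to emulate inter-animal variability in electrode
impedance and signal amplitude, which is exactly what per-animal
calibration exists to absorb.

What the generator does **not** emulate: realistic EEG waveforms (spindles,
K-complexes, phasic REM events), circadian structure, gradual state
transitions, electrode drift, or non-stationary artifacts. Passing tests
therefore demonstrate that the pipeline's logic and statistics are correct
under its stated spectral assumptions — not that the thresholds would
separate states on any particular real recording.

**The plant's response to stimulation** is probabilistic and
state-dependent, not deterministic: while the platform is moving and the
animal is in REM, each 100 ms control cycle terminates the bout (to Wake)
with probability `arousal_prob` (default 0.4). Markov transitions happen
only at epoch boundaries; arousal is evaluated every cycle — the two time
scales of the control design. An optional linear decline of `arousal_prob`
with elapsed time (floor at 10 %) emulates rising homeostatic REM pressure
during prolonged deprivation, reproducing the qualitative attenuation of
suppression in longer protocols; it is disabled by default. Motion artifact
— band-limited 90–200 Hz noise at `artifact_hf_gain` RMS (default
0.1 mV) — is injected whenever the actuator is not idle.

## The control loop and actuator

The loop runs in simulated time, one 100 ms tick per cycle, so day-long
sessions take minutes of CPU; the real system's ~20 ms compute budget and
sub-millisecond TTL latency are hardware figures that have no software
analogue here and are not asserted in tests. Each cycle: plant step →
synthesis of the next 100 samples (with artifact while shaking) → window
update → PSD → features → classification → TTL trigger high *iff* the
decision is REM → actuator update. The trigger is level-held (high exactly
while REM is decided); minimum-on-time and refractory logic were considered
and left out as the paper's simplest reading, and the level-triggered
contract is what the tests pin down. The actuator ramps linearly at
523.6 rad/s² to 8000 rpm (reached in 1.6 s) on a high trigger and stops
within one cycle on a low one; through the 103:1 gear reduction the cam
turns at 77.7 rpm, one platform oscillation per revolution (1.3 Hz). The
cam geometry (15/10 mm elliptical axes) implies a 5 mm peak-to-peak
displacement while the hardware characterization reports 10 mm;
`cam_kinematics()` reports both values side by side rather than silently
reconciling them. A pre-run self check verifies a live signal source,
finite features, and the trigger path via a ~5 s actuation burst, and the
loop refuses to start if any check fails. The termination condition is a
maximum duration plus an optional cumulative-REM cap.

One deliberate identity: the loop draws its Markov transitions from the
same seeded uniform stream as `generate_hypnogram()`, so a session with
`arousal_prob = 0` reproduces the unstimulated hypnogram epoch for epoch.
That turns "stimulation has no effect when arousal is impossible" from a
statistical claim into an exact one.

## Validation statistics

Offline evaluation mirrors the device study: epoch-level confusion matrices
(row-normalized over true states) with per-state recall, precision and F1;
state occupancy; per-animal baseline-to-deprivation fold changes
summarized by geometric means with bias-corrected percentile bootstrap 95 %
CIs (10,000 seeded resamples on the log ratios; the CI method is the
package's choice — only "95 % CI" is inherited); and exact paired Wilcoxon
signed-rank tests (dynamic-programming enumeration of the null up to 25
pairs, Pratt handling of zero differences, midranks for ties). The same
baseline/deprivation orientation is used for every state, so selective REM
suppression shows as a large REM ratio with Wake and NREM near unity. When
an animal has zero REM epochs in a deprivation session, half of one
epoch's occupancy is added to both members of that pair to keep the ratio
finite; the number of adjusted pairs is reported. A long-format
(θ/δ ratio, EMG RMS, state) export reproduces the two-dimensional
state-space view in which the REM cluster empties out under deprivation.

## Problem sizes and numerical choices

Simulated experiments use desk-scale sessions chosen once: cohorts of 8
virtual animals; a 24 h baseline *hypnogram* per animal as the occupancy
reference; continuous signals materialized for a calibration slice of at
least 1.5 h, extended in 10 min steps until it holds ≥ 50 REM and ≥ 200
NREM epochs (the in-silico analogue of acquiring additional baseline data
when a session under-samples a state); a separate validation session under
the same rule; and 1.5 h closed-loop deprivation sessions. At these sizes
the full acceptance study runs in a few minutes while the key statistics
are stable: baseline REM occupancy 6.6 ± 1.0 % across animals against the
7 % stationary target, and a REM fold change comfortably above 10 with the
95 % CI excluding 1.

Numerical details worth knowing: band-edge comparisons use a 1e-9 Hz guard
against floating-point drift on the 0.1 Hz grid; `fold_change()` returns a
degenerate CI equal to the point estimate when all log ratios are equal;
the Wilcoxon enumeration doubles midranks to work on integers; and all
randomness — chain, synthesis, arousal, bootstrap — flows through explicit
seeds, with the control loop keeping its chain and signal streams separate
so that changing the plant's response never re-randomizes the underlying
sleep trajectory.

One caveat on a documented sanity bound: adding a REM epoch above the
current REM mean can raise $\tau_{\theta/\delta}$ by *more* than it raises
the mean when the new point lies close to the mean (the sample SD can
shrink). The bound holds once the added point is at least
$s\sqrt{(n+1)/n}$ above the mean, and that is the form the test suite
asserts.

## Known limitations

The synthetic EEG is a spectral caricature; classification performance on
it says nothing quantitative about any real recording. The plant has no
REM rebound dynamics beyond the optional arousal decline, no circadian
modulation, and its bout statistics are exponential by construction.
Thresholds are static per session — the underlying protocol explicitly
avoids recalibration from shaking epochs, and adaptive thresholding is out
of scope. EDF input/output is not provided; signals are exchanged as
float32 binary with a JSON sidecar.
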