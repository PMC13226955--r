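# remloop

Closed-loop REM sleep deprivation for mice, simulated end to end.

Selective REM deprivation experiments increasingly use closed-loop devices:
EEG is classified in real time and a mechanical stimulus (here, a shaking
home-cage platform) fires only while REM sleep is detected, sparing NREM
sleep and wakefulness. Developing, tuning and validating such a system on
live animals is slow and expensive. remloop re-creates the whole system in
software for sleep researchers and instrument builders: a "virtual mouse"
generates state-dependent EEG/EMG with a known ground-truth hypnogram, the
real-time pipeline classifies it exactly as the device would, a simulated
actuator executes the motion profile, and the analysis layer computes the
statistics used to report deprivation efficacy. Every stage is testable at
desk scale, with seeds controlling all randomness.

## The method

EEG sampled at 1 kHz is analyzed in a 5 s sliding window advanced every
100 ms (98 % overlap). Each window is Hanning-tapered, zero-padded to
10,000 points (0.1 Hz bins), and reduced to two features:

- **θ/δ ratio** R<sub>θ/δ</sub> = P[4–8 Hz] / P[0.5–4 Hz] — high in REM;
- **HF fraction** R<sub>HF</sub> = P[90–200 Hz] / P[0.5–500 Hz] — high in
  wake and during motion artifact.

The decision rule is a total partition with per-animal thresholds:

    Wake  if R_HF >= tau_HF
    REM   if R_theta/delta >= tau_td  (and R_HF < tau_HF)
    NREM  otherwise

with tau_td = mean(R<sub>θ/δ</sub> in REM) − sd, and tau_HF =
mean(R<sub>HF</sub> in NREM) + sd, estimated from a labeled baseline
recording per animal. A TTL trigger is held high while REM is decided,
driving a cam-based shaker (8000 rpm motor through a 103:1 reduction:
77.7 rpm cam, 1.3 Hz platform oscillation, 1.6 s ramp at 523.6 rad/s²).
Decisions are aggregated into 2.5 s epochs (25 per epoch, majority vote)
for offline scoring; efficacy is reported as per-animal
baseline-to-deprivation occupancy fold changes with geometric means,
bootstrap CIs and paired Wilcoxon signed-rank tests.

## Worked example

```r
library(remloop)

m <- default_animal_model()                        # the virtual mouse
baseline <- generate_hypnogram(m, duration_s = 3600, seed = 1)
sig <- synthesize_signals(baseline, m, seed = 1)
th <- calibrate_animal(sig$eeg, baseline, animal_id = "demo-mouse")
th
#> <remloop_thresholds> demo-mouse: tau_theta_delta = 4.557, tau_hf = 0.008428

occupancy(baseline)
#> # A tibble: 3 × 3
#>   state n_epochs   pct
#> 1 REM         74  5.14
#> 2 Wake       674 46.8
#> 3 NREM       692 48.1

sess <- run_control_loop(m, th, duration_s = 3600, seed = 2)
sess
#> <remloop_session> animal-01: 36000 cycles (60.0 min), plant REM 0.31%,
#>   3 trigger events, termination: max_duration
```

The hour of simulated baseline sleep contains 5.1 % REM; under closed-loop
control the same animal's REM occupancy drops to ~0.3 %: the classifier
detects each REM bout within a few seconds (the sliding window must fill
with REM-like signal first), the trigger fires, and the probabilistic
arousal response of the plant terminates the bout. `glance(sess)` returns
the one-row session summary (occupancies, trigger count, clipped samples);
`autoplot(sess)` draws the predicted-vs-truth hypnogram with the trigger
raster, and `autoplot(confusion_matrix(...))`,
`plot_state_space(state_space_export(...))` and
`autoplot(efficacy_report(...))` reproduce the standard validation
figures. The full study — 8 jittered animals, calibration, validation
gate, deprivation, statistics — is one call:
`simulate_deprivation_cohort(n_animals = 8, seed = 1)`.

A thin CLI wraps the same functions
(`exec/remloop simulate|calibrate|run-loop|validate|efficacy|self-check`).

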