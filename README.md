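# bfrsprint

Analysis pipeline for repeated cycling sprint tests to exhaustion performed
under blood flow restriction (BFR): partial vascular occlusion of the
proximal lower limbs, expressed as a percentage of the resting
pulse-elimination pressure (typically 0 / 45 / 60 %). The protocol is 10-s
all-out sprints with 20-s active recovery until task failure (cadence
< 70 rpm), with near-infrared spectroscopy (NIRS) of the vastus lateralis
and prefrontal cortex, breath-by-breath gas exchange, and a pre/post
neuromuscular assessment by femoral-nerve stimulation.

The package is aimed at exercise physiologists who need a tested, reusable
implementation of this analysis chain, and ships a synthetic-data generator
that emulates every recorded channel with known ground truth, so the whole
pipeline is verifiable without access to human recordings.

## What it computes

**Sprint performance.** Per-sprint mean/peak power, total work (kJ), and the
fatigue index (percent decrement)

    S_dec (%) = [1 − S̄ / S_best] × 100

where `S̄` is the mean of all per-sprint mean powers and `S_best` the higher
mean power of the first two sprints. Also: the 95 % anti-pacing check
against the best warm-up sprint, task-failure detection from cadence,
peak oxygen uptake as the highest 30-s average over irregular
breath-by-breath data, and the lowest stable pulse-oximetry value of the
final minute.

**NIRS oxygenation.** Channels are low-pass filtered with a 4th-order
zero-phase Butterworth filter (0.2 Hz cutoff, forward–backward), sprint
phases are segmented automatically from the deoxyhemoglobin signal (or
taken from the ergometer log), and each sprint contributes
`Δ = max − min` for Δ[O₂Hb], Δ[HHb], Δ[tHb] (= O₂Hb + HHb) plus the
absolute TSI maximum. Per-sprint series are normalised to set-duration
fractions (20/40/60/80/100 % of sprints completed) with linear
interpolation at fractional indices.

**Neuromuscular fatigue.** MVC force, superimposed-doublet and resting
evoked amplitudes (P100, P10, single twitch), the corrected
interpolated-twitch voluntary activation

    VAL (%) = [1 − superimposed × (voluntary at stimulation / MVC)
                   / potentiated resting doublet] × 100,

the low-frequency fatigue ratio P10/P100, EMG RMS over the 250-ms epoch at
peak force, and RMS normalised by the M-wave peak-to-peak amplitude.

**Group inference.** Linear mixed-effects models with a participant random
intercept (lme4), likelihood-ratio tests of each fixed effect (full vs
reduced model, ML fits), Tukey-adjusted least-squares-means contrasts
(emmeans, Satterthwaite df), and per-subject percent-change summaries
versus the unoccluded condition.

## Worked example

```r
library(bfrsprint)

# one synthetic repeated-sprint test: 8 sprints, 5% per-sprint decrement
rst <- generate_power_profile(n_sprints = 8, peak_power = 650,
                              decrement_rate = 0.05, noise_sd = 15, seed = 42)
psp <- per_sprint_power(rst$power, rst$timeline)
round(psp$mean_w, 1)
#> [1] 650.5 616.2 587.9 558.5 529.5 505.2 477.2 454.2
fatigue_index(psp$mean_w)     # 15.8 (%)
total_work(rst$power, rst$timeline)  # 43.8 (kJ)

# muscle NIRS locked to the same timeline, with pedal artifact and noise
nirs <- generate_nirs_traces(rst$timeline,
                             delta_schedule = seq(10, 6.5, length.out = 8),
                             artifact_amp = 3, noise_sd = 0.2, seed = 42)
hhb_f <- lowpass_zero_phase(nirs$hhb)
tl <- segment_sprints(hhb_f)    # detects all 8 sprints
round(sprint_deltas(hhb_f, tl), 2)
#> [1] 9.99 9.55 9.01 8.52 8.01 7.53 6.98 6.43
round(normalize_set_duration(sprint_deltas(hhb_f, tl)), 2)
#>  20%  40%  60%  80% 100%
#> 9.72 8.91 8.11 7.31 6.43

# neuromuscular assessment round trip
nm <- generate_neuromuscular_traces(mvc_true = 300, val_true = 85, p100 = 60,
                                    p10 = 54, twitch = 30, seed = 42)
a <- analyze_neuromuscular(nm$force, nm$emg, nm$markers, phase = "pre")
#> MVC 300 N  VAL 85.0%  P10/P100 0.90  RMS/M-wave 0.060
```

The per-sprint power means fall geometrically from 650 W as injected; the
fatigue index summarises that decrement in one number. The filtered
deltas recover the injected 10 → 6.5 μM deoxygenation schedule to within
a few hundredths of a μM, and the neuromuscular metrics reproduce the
injected activation state exactly in the noise-free limit.

A full study (participants × conditions, all channels) comes from
`generate_study()` / `run_generate()`, and `run_analyze()` produces the
per-test summary tables, normalised NIRS tables, and the mixed-model
effects/contrasts tables in one call.

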