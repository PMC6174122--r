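---
title: "Methods: repeated-sprint analysis under blood flow restriction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeated-sprint analysis under blood flow restriction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfrsprint)
```

This vignette documents the models, conventions and numerical choices
behind `bfrsprint`: what each stage computes, why the defaults are what
they are, what the synthetic-data generator does and does not emulate, and
which parts of the design were genuinely open choices.

## The protocol being analysed

A repeated-sprint test (RST) consists of 10-s all-out cycling sprints
separated by 20-s active recovery at a fixed 20 W ergometer resistance,
continued until volitional exhaustion or task failure, operationalised as
cadence below 70 rpm. Tests are performed under bilateral blood flow
restriction (BFR) at 0, 45 or 60 % of the resting pulse-elimination
pressure. Around the test sit a two-sprint warm-up (used by the
anti-pacing check), NIRS recordings of the vastus lateralis and prefrontal
cortex, breath-by-breath gas exchange, heart rate and pulse oximetry, and
a pre/post neuromuscular assessment on a force chair with femoral-nerve
stimulation.

## Sampling conventions

All traces are uniformly sampled `channel_trace` objects; sample `i` sits
at `(i-1)/fs` seconds. Every per-sprint window is half-open, `[start,
end)`, so the boundary sample between a sprint and its recovery is counted
exactly once. Two consequences worth knowing: the rectangle Riemann sum
over such a window is the exact discrete integral (a constant `P` over a
`D`-second sprint contributes `P × D` of work), and the generator scales
its amplitudes against the sampled window so round trips are exact rather
than merely close.

## NIRS processing

**Filtering.** The analysis filter is a 4th-order low-pass Butterworth at
0.2 Hz applied forward and backward (zero phase). Filter design comes from
the signal package; the forward–backward application is implemented here
because robust edge handling matters for the first and last sprint: the
input is extended by odd symmetry (3 × filter length samples at each end)
and each pass is initialised at its steady state for the first sample's
level. A constant trace therefore comes back bit-for-bit unchanged, and an
isolated slow peak is not displaced by more than one sample. The effective
magnitude response is the square of one order-4 pass: at 0.02 Hz the loss
is below 1 %, at the 1.4 Hz pedal-stroke frequency attenuation exceeds
100 dB.

**Segmentation.** When an ergometer log is available its timeline is used
verbatim. Otherwise sprints are detected from the filtered \[HHb\] signal,
which rises during each sprint and relaxes during recovery. Prominent
local maxima separated by at least 0.7 × the expected 30-s cycle mark
sprint ends. The prominence threshold is 3 × a robust scale (MAD) of the
filtered first difference, aggregated over one expected cycle; on sprint
recordings this self-scales with signal amplitude and sits a factor ≈ 2
below true sprint prominences, while rejecting filter-ripple peaks in the
lead-in. A perfectly flat signal yields an empty timeline with a warning.
A trace containing *only* noise is not reliably rejected — from a single
filtered channel there is no absolute noise reference — and downstream
sanity checks on delta magnitudes are the intended guard there.

Onsets are *not* taken at the smoothed local minimum: the minimum of the
filtered signal is biased early because the curvature on the rise side of
the valley exceeds that on the recovery side. Instead the onset is placed
half a nominal sprint duration before the half-rise crossing of the
\[HHb\] upstroke. The half-rise point of a near-symmetric transition is
preserved by a zero-phase filter and sits where the slope is largest, so
additive noise perturbs it least; under the package's default noise
conditions onset errors stay below ±0.2 s, against a ±0.5 s design target.
The nominal sprint duration (10 s) is protocol knowledge, which is
acceptable for this use; for protocols with very different work/rest
geometry the parameter must be set accordingly.

**Deltas.** Each sprint contributes `Δ = max − min` of the filtered trace
within the sprint window — unsigned, so the desaturation direction is not
constrained — for Δ\[O₂Hb\], Δ\[HHb\] and Δ\[tHb\], where tHb is the
pointwise chromophore sum. TSI is summarised both as Δ and as the
per-sprint absolute maximum, since the absolute saturation level carries
meaning of its own. Differential pathlength factors (4.0 muscle, 6.0
cerebral) are instrument metadata: inputs are already concentration
changes, so they are carried through, never applied.

**Set-duration normalisation.** Because each participant completes a
different number of sprints, per-sprint series are re-expressed at 20, 40,
60, 80 and 100 % of the completed set. Fraction `f` maps to the 1-based
sprint index `p = f·n`; fractional `p` interpolates linearly between
neighbouring sprints, `p < 1` clamps to the first sprint, and `f = 1`
returns the final sprint exactly. This convention makes `n = 5` and
`n = 10` align exactly with sprints (1..5) and (2,4,6,8,10) respectively.

## Sprint performance endpoints

The fatigue index is `S_dec = (1 − S̄/S_best) × 100` with `S_best` the
higher mean power of the *first two* sprints (an anti-pacing definition: a
slow first sprint cannot inflate the index). It is scale-invariant and
zero exactly when all sprints equal the best. Peak oxygen uptake is the
maximum 30-s time-weighted average of the breath-by-breath step function,
with windows anchored at every breath — equivalent to, and tested
against, a brute-force scan of all windows. The "lowest stable value" of
pulse oximetry in the final minute is operationalised as the minimum mean
over runs of ≥ 3 consecutive samples whose range is ≤ 2 percentage
points; with no stable run the plain minimum is returned with a warning.
Task failure requires cadence below threshold for a sustained dwell
(default 1 s) so single-sample dropouts cannot terminate a test.

## Neuromuscular assessment

The assessment is: MVC with a superimposed 100 Hz doublet at peak force,
then resting 100 Hz doublet (P100), 10 Hz doublet (P10) and single twitch
at 2-s spacing. Evoked amplitudes are peak force within 0.5 s after the
stimulation minus a 100-ms pre-stimulus baseline; the baseline window ends
50 ms before the marker so that marker jitter of ±50 ms cannot
contaminate it. Voluntary activation uses the corrected
interpolated-twitch formula, scaling the superimposed amplitude by the
ratio of voluntary force at stimulation to peak MVC; the uncorrected
classic form is available via `corrected = FALSE`. The potentiated
resting doublet is the post-MVC resting P100 — the stimulation order
makes it the potentiated response. Values above 100 % (negative
superimposed estimates under noise) clamp to 100 with a warning rather
than erroring, since they occur legitimately in noisy recordings; an
apparent *increase* in activation pre→post is flagged in output, not
corrected. EMG RMS uses the 250-ms epoch centred on peak voluntary force,
and is normalised by the M-wave of the resting single twitch (the
stimulation whose M-wave is least contaminated by preceding activity);
which stimulation normalises is configurable.

## Statistical inference

Endpoints are modelled as `value ~ condition (× time or × set-duration
fraction) + (1 | participant)`. Fixed-effect tests are likelihood-ratio
tests of the full model against the model without the effect in question,
both fitted by maximum likelihood — REML likelihoods are not comparable
across fixed-effect structures, so `lrt_effect()` refuses REML fits.
Variance components, when they are the quantity of interest, use REML.
The chi-square reference for the LRT is the standard choice; at 11
participants it is mildly anticonservative (simulated type-I error ≈ 0.06
at nominal 0.05), which the calibration test bounds explicitly.
Pairwise comparisons are Tukey-adjusted least-squares means with
Satterthwaite degrees of freedom — an approximation, adopted because it
is the common default for mixed models. Set-duration is treated as a
categorical factor (numeric coding available by passing it as such).
Percent changes are computed per subject and then averaged — matching the
mean ± SD style of reporting — which is not the same number as the ratio
of group means.

## The synthetic-data generator

The generator's role is to produce study-shaped data with known ground
truth. Design choices:

* **Power.** Each sprint is a trapezoid (0.5-s rise, then plateau) whose
  plateau is scaled so the *sampled mean power* of sprint `k` equals
  `peak × (1 − d)^(k−1)` exactly; the fatigue index of the noise-free
  profile is then available in closed form. Recovery sits at the
  ergometer's 20 W. Cadence is high during sprints and, by default, dips
  below the failure threshold at the end of the final sprint, emulating
  test termination.
* **NIRS.** Sprint responses are raised-cosine rises with zero slope at
  both sprint boundaries; each recovery relaxes 90 % of the rise, again
  with zero boundary slope. The signal is therefore continuously
  differentiable with spectral content concentrated far below the 0.2 Hz
  cutoff, so the analysis filter preserves per-sprint deltas to within a
  few hundredths of a μM. An earlier mono-exponential design (time
  constants of a few seconds) was rejected: its slope discontinuities at
  phase boundaries interact with the 0.2 Hz filter to attenuate deltas by
  up to ~10 % and bias detected onsets by more than a second, which would
  conflate generator artefacts with pipeline error. Amplitudes are scaled
  so the sampled max − min per sprint equals the requested schedule
  exactly; pedal-stroke artifact (default 1.4 Hz, 3 μM), linear drift and
  Gaussian noise (0.2 μM) are superimposed. The noise-free component of
  every trace is stored alongside, so recovery tests never re-derive
  ground truth from noisy data.
* **Neuromuscular.** The superimposed increment is obtained by inverting
  the activation formula at the requested VAL (so VAL = 100 gives a zero
  increment); evoked responses are twitch-shaped transients whose sampled
  peaks hit the requested amplitudes exactly; EMG is band-limited
  (20–450 Hz) Gaussian activity rescaled so the RMS over the analysis
  epoch is exact, plus a biphasic M-wave with exact peak-to-peak
  amplitude. No EMG stimulation artifact is modelled for the superimposed
  doublet, keeping the RMS epoch a purely voluntary segment.
* **Study level.** Endpoint truth is drawn from a Gaussian generating
  model: participant random intercept plus residual, with condition
  effects applied multiplicatively to the participant's own level (so
  per-subject percent changes centre on `1 − multiplier`), or additively
  where configured. With all multipliers at one this is exactly the
  additive mixed model the inference stage assumes — the regime used for
  type-I-error calibration. Defaults are patterned after group statistics
  typical of BFR repeated-sprint studies (e.g. sprint count dropping
  ~47 % at 45 % occlusion and ~66 % at 60 %, voluntary activation falling
  to ~72 % post-test at 60 %); they are presets for validation, not
  claims about any particular dataset. Per-sprint NIRS kinetic parameters
  have no published reference values; those defaults are presets too.

What the generator does **not** emulate: instrument physics (modified
Beer–Lambert conversion), cuff-pressure hemodynamics, cardiorespiratory
coupling, motion artifacts other than the sinusoidal pedal component, and
any sex structure. Passing tests on this generator therefore demonstrates
correctness of the *analysis chain* under controlled conditions, not
robustness to every failure mode of field recordings.

## Calibration problem sizes

The package's own validation uses: 10 synthetic tests of 5–30 sprints for
NIRS recovery; 1000 null studies of 11 participants for type-I error of
the condition LRT (accepted range 0.037–0.064, the 95 % binomial band
around 0.05) plus 200 studies under the default effect preset for power;
800 replicate studies of 50 participants for 2-standard-error coverage of
fixed effects (REML); and 5 replicate studies of 50 participants for
random-intercept SD recovery within 20 % (the median is compared, since a
single replicate's SD estimate has ≈ 10 % sampling error of its own).
These sizes keep the default suite comfortably inside a few minutes on one
CPU while leaving the Monte-Carlo error well below the tested margins.

## Known limitations

* Automatic segmentation assumes the protocol's nominal sprint duration
  and an approximate 30-s cycle; strongly irregular protocols need the
  ergometer timeline.
* The LRT's chi-square reference is anticonservative at small n; a
  parametric bootstrap would tighten it but is not implemented.
* `vo2_peak` treats each breath's value as holding until the next breath;
  alternative interpolation conventions shift the result by a fraction of
  one breath.
* The pacing check and warm-up handling operate on summary peaks, not on
  raw warm-up traces.
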