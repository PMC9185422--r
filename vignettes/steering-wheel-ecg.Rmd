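---
title: "Methods: reliability analysis of steering-wheel ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reliability analysis of steering-wheel ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steerecg)
```

## The problem

Electrodes embedded in a steering wheel can record a driver's ECG without
any body-worn sensor, but the recording is only intermittently usable:
hands leave the wheel (dropouts), steering movements produce motion
artifacts, and the pickup attenuates the cardiac signal relative to a chest
lead. The practical question is therefore not "can we record an ECG?" but
*for what fraction of the driving time is the recording reliable enough to
report a heart rate?*

`steerecg` implements the full analysis chain that answers this question on
dual-channel recordings (chest reference + wheel):

1. **R-peak detection** by a bank of classical detectors,
2. **STAPLE fusion** of the detector annotations into a probabilistic
   consensus with per-detector sensitivity/specificity estimates,
3. **harmonic SNR** of the wheel channel against the reference heart rate,
4. **rule-based usability classification** of each beat and minute,
5. **scenario-level reporting** of usable minutes and percentages.

Because the original recordings are an external deposit, the package ships
a synthetic session generator with known ground truth; every quantitative
claim in the test suite is made against that generator.

## The synthetic session generator

`generate_clean_ecg()` builds the cardiac signal as a sum of per-beat
PQRST templates: five Gaussian bumps (P +, Q −, R +, S −, T +) with fixed
offsets and widths relative to the R centre. This is deliberately not a
biophysical model — it is smooth, analytically known, and rich enough in
QRS-band energy to exercise every detector front end. Inter-beat intervals
are `60 / base_hr` seconds perturbed by independent zero-mean Gaussian
noise with standard deviation `60 * hr_sd / base_hr^2`, the first-order
mapping of a bpm-scale variability onto the interval scale. The truth
R-peak positions are the exact template centres, so detector scoring has a
noise-free oracle.

The cohort generator (`study_subjects()`) draws resting heart rates around
72 ± 8 bpm and beat-to-beat variability of 0.5–1.5 bpm. The variability
range matters: the usability classifier flags any RR-interval change above
0.08 s, so the cohort's physiological RMSSD (≈ `sqrt(2) * 60 * hr_sd /
base_hr^2`, here roughly 10–35 ms) must sit clearly below that threshold,
as it does in healthy adults under the sympathetic activation of driving.
A cohort with resting-style RMSSD near 70 ms would trip the jump rule on
physiology alone and turn the classifier into a noise generator.

`generate_scenario_noise()` adds the wheel channel's contamination:

* Gaussian broadband noise (`noise_sd_wheel`, mV),
* sinusoidal baseline wander (`wander_amplitude`, `wander_freq`),
* motion-artifact bursts — Poisson arrivals, 0.3–1 s Gaussian-enveloped
  tone bursts of 0.6–1.5 mV at 3–10 Hz,
* dropouts — Poisson arrivals with exponential lengths, inside which the
  cardiac signal is replaced by noise only (contact loss, not a zeroed
  trace, so detectors see realistic noise rather than a trivially flat
  line).

The wheel channel is `wheel_attenuation × clean + contamination`; the
reference is `clean` plus mild noise. Per-subject attenuations of
0.25–0.45 reflect the smaller R amplitudes seen through dry wheel
electrodes.

### Default scenario profiles and their calibration

The four default profiles fix the session layout of the emulated study:
rest 5 min, city/highway/rural 15 min each (19 subjects × 50 min =
950 min). Contamination rates are ordered rest < city ≈ highway ≈ rural
and were calibrated once, against the full 19-subject default study, so
that the usability pipeline classifies roughly 40–60 % of the driving time
as reliable — the regime the method is designed to discriminate in. The
dominant lever is the density of localized events (dropouts ≈ 0.7–0.8/min,
artifacts ≈ 2/min for driving): each event damages a handful of
consecutive beats, and a 60-s window fails once more than 10 % of its
beats are damaged. Broadband noise is kept low enough (0.03–0.04 mV
against R amplitudes of 0.2–0.5 mV) that detection between events is
near-perfect; diffuse noise would degrade every window a little instead of
a few windows a lot, which is not how contact artifacts behave.

What the generator does **not** emulate: realistic QRS morphology changes,
ectopic beats, electrode polarization drift, powerline interference, or
autocorrelated heart-rate dynamics (an AR(1) option was considered and
dropped — independent perturbations already make the 0.08 s rule
non-trivial). Passing tests therefore demonstrate the *pipeline's*
correctness and its behaviour under the stated contamination model, not
detector performance on pathological ECG.

## Preprocessing

The analysis band is 0.5–25 Hz (baseline wander below, broadband noise
above). `bandpass()` applies a Butterworth filter of order 4, realized as
a high-pass/low-pass cascade in closed-form second-order sections. The
narrow low edge (0.5 Hz at fs = 500, i.e. 0.002 of Nyquist) makes the
single order-8 transfer polynomial numerically ill-conditioned — in
transfer-function form the filter is linear only to ~1e-5 relative, while
the biquad cascade holds 1e-9, which the test suite asserts. Zero-phase
(forward–backward) application is the default so that R-peak timing is
unshifted, at the cost of doubling the effective order; 5 s of reflect
padding absorbs the startup transient. Both channels are filtered
identically (the filtering question is configurable per call).

## The detector bank

Three heterogeneous classical detectors are implemented behind one
interface; the bank is extensible and all fusion code is agnostic to the
number of raters (two is the minimum for STAPLE).

* `detect_pan_tompkins()`: 5–15 Hz bandpass → derivative → squaring →
  150 ms moving-window integration → adaptive dual thresholds (running
  signal/noise peak estimates) with search-back, 200 ms refractory.
* `detect_derivative()`: squared first derivative, threshold a fraction of
  a running maximum with 1.5 s exponential forgetting, 200 ms refractory.
* `detect_shannon_energy()`: Shannon energy `-d² log d²` of the normalized
  derivative, smoothed into a 120 ms envelope, adaptive threshold as
  above.

Each detector refines its detections to the local maximum of its
bandpassed signal within ±50 ms (ties broken to the earliest index),
enforces the refractory by keeping the higher-amplitude peak, and discards
detections within 0.3 s of the recording edges where filter transients
live. The 1.5 s threshold memory is a deliberate compromise: long memories
make large artifacts blind a detector for many seconds afterwards, short
memories chase noise.

## STAPLE fusion

STAPLE is formulated for per-item binary decisions, but detectors emit
point events. `build_decision_matrix()` adapts: all detector peaks are
pooled and single-linkage clustered — any chain of peaks whose consecutive
gaps are below 50 ms (about half a QRS width) forms one candidate event,
represented by the median member index. `votes[c, d] = 1` iff detector *d*
contributed a peak to candidate *c*.

`staple_em()` then runs expectation-maximization over the binary model:
detector *d* has sensitivity `p[d]` (votes on a true beat) and specificity
`q[d]` (stays silent on a non-beat candidate). The E-step computes each
candidate's posterior probability of being a true beat from the current
`(p, q)` and a prior; the M-step re-estimates `(p, q)` from the
posteriors. The prior defaults to the fraction of candidates carrying at
least half the votes, clamped to [0.05, 0.95]; iteration stops when
`(p, q)` moves less than 1e-6 or after 100 rounds; estimates are clamped
to [1e-6, 1 − 1e-6] so unanimous columns cannot produce log(0). The
algorithm is deterministic, its log-likelihood is non-decreasing (asserted
in tests), and candidates with posterior ≥ 0.5 form the consensus —
exactly a weighted majority vote. `consensus_refine()` finally snaps
consensus indices onto the bandpassed waveform (±50 ms; collisions keep
the higher posterior).

Two scope decisions deserve emphasis. First, there is no background grid
of non-events: specificity is defined over the candidate set only, so `q`
estimates are informative about disagreement among detectors, not about
silence on empty signal — a documented limitation that does not affect the
consensus. Second, fusion is run on both channels: the reference consensus
is the ground-truth surrogate, and the wheel consensus feeds the wheel
heart-rate series that the usability rules judge.

## SNR

The wheel channel's SNR is `10·log10(P_signal / P_noise)` per 60-s
segment, from a raw periodogram. `P_signal` is the power inside harmonic
bands `k·f0 ± 0.2 Hz`, `k = 1..5`, with the fundamental `f0` taken from
the reference channel's mean heart rate over the segment; `P_noise` is
the remaining power inside the 0.5–25 Hz analysis band. The harmonic
partition (how many harmonics, how wide a band) is this package's concrete
definition of a quasi-periodic SNR and is fully configurable via
`snr_spec()`, because published dataset-level values depend on that choice.
The recording-level value is the arithmetic mean of segment dB values (not
the dB of mean powers — segments are equally weighted regardless of their
absolute power). Non-positive noise power (pure tones) clamps to +99 dB
with a warning. Note that even a noise-free ECG scores below 0 dB under
this definition: QRS energy above the fifth harmonic counts as noise, which
is consistent with the negative dataset-level values this kind of analysis
reports.

## Usability rules

Per-beat classification (`classify_beats()`) marks a beat unreliable when
any of three separable rules fires:

* **RRI jump**: the RR interval changes by more than 0.08 s between
  consecutive beats — the primary rule; on the reference channel this rule
  is skipped (the chest lead is trusted by construction).
* **HR tube**: the beat's heart rate leaves a ±10 bpm tube around the
  median reference heart rate.
* **Amplitude**: the beat amplitude exceeds 3× the median beat amplitude.

The tube half-width and the amplitude factor are package choices — the
rule is usually stated as "a tube around the median reference heart rate
that excludes excessive amplitudes" without either constant being
quantified — so both are configurable and independently switchable in
`usability_rules()`. The 60–100 bpm "normal range" is used
only as a sanity warning on the reference median, not as a rejection rule.

`usable_time()` converts beat labels into minutes: non-overlapping 60-s
windows, a window usable iff it contains at least one beat and ≥ 90 % of
its beats are reliable. The window/threshold pair is the package's
aggregation convention for minute-level bookkeeping; monotonicity in the
jump threshold and the [0, 1] range of the usable fraction are asserted as
properties.

## Reporting

`summarize_scenario()` pools subjects (total and usable minutes, usable
percentage rounded to two decimals, mean SNR); `summarize_study()` reports
the headline driving percentage as the *unweighted mean of the three
driving scenarios' rounded percentages* — not minute-weighted pooling.
With three equal-length driving scenarios the two readings differ only in
the second decimal; the unweighted mean of rounded percentages is the
reporting convention this package implements, and the raw minute totals
are returned alongside so either pooling can be recomputed. Rest is excluded (it is not driving time).
`daily_usable_minutes` scales the percentage to an assumed 30 min of
driving per day; the multiplication is reported unrounded.

## Numerical and design choices, in one place

* Sample indices are 1-based everywhere, including on-disk annotation
  CSVs; intervals are half-open `[start, end)`.
* Filters: Butterworth in second-order sections; zero-phase by default;
  reflect padding; cutoffs validated against Nyquist.
* Detector tie-breaks: equal-height maxima resolve to the earliest index;
  refractory conflicts resolve to the higher amplitude.
* STAPLE: prior auto-estimated and clamped; `(p, q)` clamped to
  `[1e-6, 1 − 1e-6]`; convergence on `(p, q)` max change < 1e-6.
* Degenerate inputs: flat or too-short recordings yield empty annotations
  with a warning, never errors; empty decision matrices refuse to fuse
  with a clear message.
* Determinism: every stochastic generator takes an explicit seed and is
  bit-reproducible; the EM itself is seed-free.

## Problem sizes used in tests and the acceptance script

The test suite runs on 10–60 s recordings (single scenarios, reduced
durations) and 20-seed suites of 30–60 s sessions; the acceptance script
runs the complete default study — 19 subjects × 50 min at 500 Hz — plus a
20-session clean suite, a 20-session noisy suite, and a 500-candidate
STAPLE recovery simulation. These sizes were chosen to estimate every
reported quantity with comfortable Monte-Carlo margins while keeping a
full from-scratch reproduction in the minutes range on one core.

## Known limitations

* Specificity estimates from STAPLE are relative to the candidate set
  (see above), so they should not be quoted as per-sample specificities.
* The harmonic SNR definition is one of several reasonable partitions;
  absolute dB values are comparable only within a fixed `snr_spec()`.
* The generator's artifact model is stationary within a scenario; real
  driving has route-correlated artifact bursts.
* Reading the deposited study recordings requires a user-supplied adapter
  (`import_external_session()` documents the extension point); the
  package does not guess an undocumented on-disk format.
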