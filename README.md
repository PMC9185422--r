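# steerecg

Reliability analysis of steering-wheel electrocardiograms.

Electrodes embedded in a car's steering wheel can record a driver's ECG with
no body-worn sensor, but only intermittently: hands leave the wheel,
steering produces motion artifacts, and the dry-electrode pickup attenuates
the cardiac signal relative to a chest lead. `steerecg` answers the
question such systems stand or fall on — *for what fraction of the driving
time is the wheel recording reliable enough to report a heart rate?*

The package implements the full analysis chain on dual-channel recordings
(chest reference + wheel, 500 Hz), and ships a synthetic driving-session
generator with known R-wave ground truth so the whole pipeline is testable
without any external data:

* **Synthetic sessions** — per-beat PQRST templates with controllable
  heart-rate profile; a wheel channel with attenuation, baseline wander,
  broadband noise, Poisson motion-artifact bursts and hands-off dropouts
  whose rates differ by scenario (rest 5 min; city/highway/rural 15 min).
* **Detector bank** — Pan–Tompkins, squared-derivative and Shannon-energy
  R-peak detectors behind one pluggable interface.
* **STAPLE fusion** — expectation-maximization over the candidate × detector
  vote matrix. Each detector *d* is modelled by a sensitivity
  `p_d = P(vote | true beat)` and specificity `q_d = P(silent | non-beat)`;
  the E-step computes each candidate's posterior `P(true beat | votes)`,
  the M-step re-estimates `(p, q)`, and candidates with posterior ≥ 0.5
  form the consensus (weighted majority voting).
* **Harmonic SNR** — per 60-s segment, `SNR = 10·log10(P_signal/P_noise)`
  dB from a periodogram, where `P_signal` is the power in bands
  `k·f0 ± 0.2 Hz` (`k = 1..5`, `f0` from the reference heart rate) and
  `P_noise` the remaining 0.5–25 Hz power.
* **Usability rules** — a beat is unreliable if its RR interval changes by
  more than 0.08 s (rule skipped on the reference channel), its heart rate
  leaves a ±10 bpm tube around the median reference HR, or its amplitude
  exceeds 3× the median; 60-s windows with ≥ 90 % reliable beats count as
  usable minutes.
* **Reporting** — per-scenario usable minutes and percentages, study-level
  headline (unweighted mean of the driving scenarios' percentages), SNR
  distribution export and plots.

All user-facing functions take and return tibbles, so analyses compose
with the pipe; the STAPLE fit supports `tidy()` and `glance()`.

## Worked example

One subject, one 5-minute city segment, end to end:

```r
library(steerecg)

sub <- subject_params("S01", base_hr = 72, hr_sd = 1, wheel_attenuation = 0.35)
profile <- scenario_profile("city", duration = 300,
  dropout_rate = 0.75, dropout_mean_len = 3, artifact_rate = 2,
  noise_sd_wheel = 0.04)
session <- generate_session(sub, list(city = profile), seed = 7)

fit <- fuse_detections(session$recordings$city_wheel)
tidy(fit)
#> # A tibble: 3 × 3
#>   detector     sensitivity specificity
#>   <chr>              <dbl>       <dbl>
#> 1 pan_tompkins       0.290       0.487
#> 2 derivative         0.960       0.217
#> 3 shannon            0.993       0.503

analyze_session(session)
#> # A tibble: 1 × 8
#>   subject_id scenario usable_minutes total_minutes usable_fraction snr_db
#>   <chr>      <chr>             <dbl>         <dbl>           <dbl>  <dbl>
#> 1 S01        city                  2             5             0.4  -4.47
#> # ℹ 2 more variables: ref_median_hr <dbl>, n_beats_wheel <int>
```

Reading the output: STAPLE estimates that the Pan–Tompkins rater fires on
only 29 % of true beats on this artifact-laden wheel channel (its adaptive
threshold is inflated by motion bursts) while the other two detectors stay
near-perfect — the consensus follows them, and its F1 against the
generator's ground truth equals the best single detector's. Downstream,
2 of the 5 one-minute windows have at least 90 % reliable beats, so 40 %
of this segment is usable, and the wheel channel runs about 4.5 dB below
its in-band noise under the harmonic SNR definition (negative values are
expected: ECG energy outside the first five harmonics counts as noise).

The full study pipeline is one call:

```r
results <- run_study(n_subjects = 19, seed = 1)    # ~minutes of compute
results |>
  dplyr::group_by(scenario) |>
  dplyr::group_map(~ summarize_scenario(.x, .y$scenario)) |>
  dplyr::bind_rows() |>
  summarize_study()
```

## Package layout

```
R/synthetic-data.R  session generator (subjects, profiles, truth)
R/io.R              canonical CSV/YAML session format + checksummed manifest
R/preprocess.R      0.5–25 Hz zero-phase Butterworth (biquad cascade)
R/detectors.R       Pan–Tompkins, derivative, Shannon-energy detectors
R/staple.R          vote-matrix construction, STAPLE EM, consensus refine
R/metrics.R         harmonic SNR, RR-interval / heart-rate series
R/usability.R       beat classification rules, usable-minute aggregation
R/report.R          scenario and study summaries, SNR distribution export
R/pipeline.R        analyze_session() / run_study() orchestration
vignettes/          methods vignette (model, assumptions, calibration)
```
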