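#' Subject parameters for the synthetic session generator
#'
#' Captures the between-subject variability that matters for wheel-ECG
#' reliability: resting heart rate, beat-to-beat variability, R-wave
#' amplitude on the chest reference, and how strongly the steering-wheel
#' pickup attenuates the cardiac signal (skin/contact properties differ
#' between drivers).
#'
#' @param subject_id Identifier string.
#' @param base_hr Mean heart rate in beats per minute, in \[40, 180\].
#' @param hr_sd Beat-to-beat heart-rate standard deviation in bpm (>= 0).
#' @param r_amplitude_ref R-wave amplitude on the reference channel, mV.
#' @param wheel_attenuation Multiplicative attenuation of the cardiac signal
#'   on the wheel channel, in (0, 1].
#'
#' @return A list of class `subject_params`.
#' @export
subject_params <- function(subject_id = "S01", base_hr = 70, hr_sd = 1,
                           r_amplitude_ref = 1.0, wheel_attenuation = 0.35) {
  if (base_hr < 40 || base_hr > 180) {
    abort("`base_hr` must lie in [40, 180] bpm.")
  }
  if (hr_sd < 0) abort("`hr_sd` must be non-negative.")
  if (wheel_attenuation <= 0 || wheel_attenuation > 1) {
    abort("`wheel_attenuation` must lie in (0, 1].")
  }
  structure(
    list(
      subject_id = subject_id, base_hr = base_hr, hr_sd = hr_sd,
      r_amplitude_ref = r_amplitude_ref, wheel_attenuation = wheel_attenuation
    ),
    class = "subject_params"
  )
}

#' Scenario noise/artifact profile
#'
#' Describes one driving scenario's contamination statistics on the wheel
#' channel: broadband noise, sinusoidal baseline wander, motion-artifact
#' bursts (Poisson arrivals), and hands-off dropout intervals (Poisson
#' arrivals with exponential lengths). The four default profiles use the
#' study durations (rest 5 min; city, highway and rural 15 min each).
#'
#' @param name Scenario name: `"rest"`, `"city"`, `"highway"` or `"rural"`.
#' @param duration Scenario duration in seconds.
#' @param dropout_rate Dropout events per minute.
#' @param dropout_mean_len Mean dropout length, seconds.
#' @param artifact_rate Motion-artifact bursts per minute.
#' @param noise_sd_wheel Broadband noise SD on the wheel channel, mV.
#' @param noise_sd_ref Broadband noise SD on the reference channel, mV.
#' @param wander_amplitude Baseline-wander amplitude, mV.
#' @param wander_freq Baseline-wander frequency, Hz.
#'
#' @return A list of class `scenario_profile`.
#' @export
scenario_profile <- function(name, duration,
                             dropout_rate = 0, dropout_mean_len = 2,
                             artifact_rate = 0, noise_sd_wheel = 0.1,
                             noise_sd_ref = 0.01, wander_amplitude = 0.2,
                             wander_freq = 0.3) {
  name <- match.arg(name, SCENARIOS)
  if (duration <= 0) abort("`duration` must be positive (seconds).")
  vals <- c(
    dropout_rate = dropout_rate, dropout_mean_len = dropout_mean_len,
    artifact_rate = artifact_rate, noise_sd_wheel = noise_sd_wheel,
    noise_sd_ref = noise_sd_ref, wander_amplitude = wander_amplitude,
    wander_freq = wander_freq
  )
  bad <- names(vals)[vals < 0]
  if (length(bad)) abort(paste0("`", bad[1], "` must be non-negative."))
  structure(
    c(list(name = name, duration = duration), as.list(vals)),
    class = "scenario_profile"
  )
}

#' Default scenario profiles
#'
#' Durations follow the study design (300 s rest, 900 s for each driving
#' scenario). Contamination rates are ordered rest < city ~ rural ~ highway
#' and are calibrated so that the usability pipeline classifies roughly half
#' of the driving time as reliable; the methods vignette documents the
#' calibration.
#'
#' @return Named list of four `scenario_profile` objects
#'   (rest, city, highway, rural).
#' @export
default_scenario_profiles <- function() {
  list(
    rest = scenario_profile("rest", 300,
      dropout_rate = 0.8, dropout_mean_len = 2.5, artifact_rate = 2.0,
      noise_sd_wheel = 0.03, noise_sd_ref = 0.01,
      wander_amplitude = 0.15, wander_freq = 0.25
    ),
    city = scenario_profile("city", 900,
      dropout_rate = 0.75, dropout_mean_len = 3.0, artifact_rate = 2.0,
      noise_sd_wheel = 0.04, noise_sd_ref = 0.01,
      wander_amplitude = 0.30, wander_freq = 0.30
    ),
    highway = scenario_profile("highway", 900,
      dropout_rate = 0.75, dropout_mean_len = 3.0, artifact_rate = 1.9,
      noise_sd_wheel = 0.04, noise_sd_ref = 0.01,
      wander_amplitude = 0.35, wander_freq = 0.35
    ),
    rural = scenario_profile("rural", 900,
      dropout_rate = 0.70, dropout_mean_len = 3.0, artifact_rate = 1.9,
      noise_sd_wheel = 0.035, noise_sd_ref = 0.01,
      wander_amplitude = 0.30, wander_freq = 0.30
    )
  )
}

# PQRST template: five Gaussian bumps, offsets/widths in seconds relative to
# the R centre, amplitudes relative to the R amplitude. Signs follow the
# canonical limb-lead morphology (P +, Q -, R +, S -, T +).
PQRST <- data.frame(
  wave = c("P", "Q", "R", "S", "T"),
  offset = c(-0.200, -0.028, 0.000, 0.030, 0.280),
  width = c(0.040, 0.010, 0.013, 0.011, 0.070),
  amp = c(0.12, -0.12, 1.00, -0.20, 0.30)
)

check_duration_fs <- function(duration, fs) {
  if (!is.numeric(duration) || duration <= 0) {
    abort("`duration` must be positive (seconds).")
  }
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be positive (Hz).")
  if (fs <= 50) abort("`fs` must exceed 50 Hz (twice the 25 Hz band edge).")
}

# Core clean-ECG synthesis without RNG management; callers own the seed.
clean_ecg_impl <- function(subject, duration, fs) {
  n <- floor(duration * fs)
  mu <- 60 / subject$base_hr
  sd_rri <- 60 * subject$hr_sd / subject$base_hr^2
  n_beats_max <- ceiling(duration / mu) + 10
  rri <- mu + stats::rnorm(n_beats_max, 0, sd_rri)
  rri <- pmax(rri, 0.25) # physical floor on the inter-beat interval
  beat_times <- 0.5 + cumsum(c(0, rri))
  beat_times <- beat_times[beat_times < duration - 0.05]
  wave <- numeric(n)
  t <- (seq_len(n) - 1) / fs
  half <- 0.45 # template support half-width, seconds
  for (tb in beat_times) {
    lo <- max(1L, floor((tb - half) * fs) + 1L)
    hi <- min(n, ceiling((tb + half) * fs) + 1L)
    tt <- t[lo:hi] - tb
    seg <- numeric(length(tt))
    for (k in seq_len(nrow(PQRST))) {
      seg <- seg + PQRST$amp[k] *
        exp(-(tt - PQRST$offset[k])^2 / (2 * PQRST$width[k]^2))
    }
    wave[lo:hi] <- wave[lo:hi] + subject$r_amplitude_ref * seg
  }
  peaks <- as.integer(round(beat_times * fs)) + 1L
  peaks <- peaks[peaks >= 1 & peaks <= n]
  list(mv = wave, truth_peaks = peaks)
}

#' Generate a clean quasi-periodic ECG with known R-peak positions
#'
#' Sums per-beat PQRST templates (five Gaussian bumps) at beat onsets whose
#' inter-beat intervals are `60 / base_hr` seconds perturbed by zero-mean
#' Gaussian noise with standard deviation `60 * hr_sd / base_hr^2` (the
#' first-order propagation of a bpm-scale variability onto the interval
#' scale). The returned truth peaks are the exact sample indices of the
#' template R centres (1-based).
#'
#' @param subject A [subject_params()] object.
#' @param duration Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed; identical inputs give bit-identical output.
#'
#' @return A list with `mv` (millivolt series) and `truth_peaks`
#'   (integer sample indices).
#' @export
#' @examples
#' sim <- generate_clean_ecg(subject_params(base_hr = 60, hr_sd = 0),
#'   duration = 10, fs = 500, seed = 1
#' )
#' diff(sim$truth_peaks) # all 500 samples = 1.0 s at 60 bpm
generate_clean_ecg <- function(subject, duration, fs = 500, seed = 1) {
  check_duration_fs(duration, fs)
  withr::with_seed(seed, clean_ecg_impl(subject, duration, fs))
}

intervals_tbl <- function(start, end, n) {
  keep <- start < n & end > 1
  start <- as.integer(pmax(1, start[keep]))
  end <- as.integer(pmin(n + 1, end[keep]))
  out <- tibble(start_sample = start, end_sample = end) |>
    arrange(.data$start_sample)
  # merge overlapping half-open intervals
  if (nrow(out) > 1) {
    merged <- list(c(out$start_sample[1], out$end_sample[1]))
    for (i in 2:nrow(out)) {
      last <- merged[[length(merged)]]
      if (out$start_sample[i] <= last[2]) {
        merged[[length(merged)]][2] <- max(last[2], out$end_sample[i])
      } else {
        merged[[length(merged) + 1]] <- c(out$start_sample[i], out$end_sample[i])
      }
    }
    out <- tibble(
      start_sample = vapply(merged, `[`, integer(1), 1L),
      end_sample = vapply(merged, `[`, integer(1), 2L)
    )
  }
  out
}

scenario_noise_impl <- function(profile, duration, fs) {
  n <- floor(duration * fs)
  t <- (seq_len(n) - 1) / fs
  noise <- stats::rnorm(n, 0, profile$noise_sd_wheel)
  if (profile$wander_amplitude > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    noise <- noise + profile$wander_amplitude *
      sin(2 * pi * profile$wander_freq * t + phase)
  }
  # motion-artifact bursts: Poisson arrivals, Gaussian-enveloped tone bursts
  n_art <- stats::rpois(1, profile$artifact_rate * duration / 60)
  art <- tibble(start_sample = integer(0), end_sample = integer(0))
  if (n_art > 0) {
    centre <- sort(stats::runif(n_art, 0, duration))
    len <- stats::runif(n_art, 0.3, 1.0)
    amp <- stats::runif(n_art, 0.6, 1.5)
    f_burst <- stats::runif(n_art, 3, 10)
    for (i in seq_len(n_art)) {
      lo <- max(1L, floor((centre[i] - len[i] / 2) * fs) + 1L)
      hi <- min(n, ceiling((centre[i] + len[i] / 2) * fs))
      if (lo > hi) next
      tt <- t[lo:hi] - centre[i]
      noise[lo:hi] <- noise[lo:hi] + amp[i] *
        exp(-tt^2 / (2 * (len[i] / 5)^2)) * sin(2 * pi * f_burst[i] * tt)
    }
    art <- intervals_tbl(
      floor((centre - len / 2) * fs) + 1L,
      ceiling((centre + len / 2) * fs) + 1L, n
    )
  }
  n_drop <- stats::rpois(1, profile$dropout_rate * duration / 60)
  drop <- tibble(start_sample = integer(0), end_sample = integer(0))
  if (n_drop > 0) {
    d_start <- stats::runif(n_drop, 0, duration)
    d_len <- stats::rexp(n_drop, rate = 1 / profile$dropout_mean_len)
    drop <- intervals_tbl(
      floor(d_start * fs) + 1L,
      ceiling((d_start + d_len) * fs) + 1L, n
    )
  }
  list(noise = noise, artifact_intervals = art, dropout_intervals = drop)
}

#' Generate scenario-dependent wheel-channel contamination
#'
#' Produces the additive contamination for one scenario: Gaussian broadband
#' noise, sinusoidal baseline wander, and high-amplitude band-limited
#' motion-artifact bursts with Poisson arrivals, plus hands-off dropout
#' intervals (Poisson arrivals, exponential lengths). Intervals are returned
#' half-open `[start_sample, end_sample)`, 1-based, clipped to the recording.
#'
#' @inheritParams generate_clean_ecg
#' @param profile A [scenario_profile()].
#'
#' @return A list with `noise` (mV series), `artifact_intervals` and
#'   `dropout_intervals` (tibbles with `start_sample`, `end_sample`).
#' @export
generate_scenario_noise <- function(profile, duration = profile$duration,
                                    fs = 500, seed = 1) {
  check_duration_fs(duration, fs)
  withr::with_seed(seed, scenario_noise_impl(profile, duration, fs))
}

apply_dropouts <- function(x, intervals, value = 0) {
  for (i in seq_len(nrow(intervals))) {
    idx <- intervals$start_sample[i]:(intervals$end_sample[i] - 1L)
    x[idx] <- value
  }
  x
}

#' Generate a full dual-channel driving session
#'
#' For each scenario, synthesizes a clean cardiac signal, records it on the
#' chest reference (clean plus mild broadband noise) and on the steering
#' wheel (clean times `wheel_attenuation`, zeroed inside dropout intervals to
#' model contact loss, plus the scenario contamination). Both channels share
#' the same ground-truth R-peak positions.
#'
#' @inheritParams generate_clean_ecg
#' @param profiles Named list with exactly one [scenario_profile()] per
#'   scenario name (as from [default_scenario_profiles()]).
#'
#' @return A list with `recordings` (named list of eight
#'   [new_recording()] objects, `"<scenario>_<channel>"`) and `truth`, a list
#'   of tibbles: `peaks` (`scenario`, `sample_index`), `artifacts` and
#'   `dropouts` (`scenario`, `start_sample`, `end_sample`).
#' @export
#' @examples
#' ses <- generate_session(subject_params(), default_scenario_profiles()["rest"],
#'   seed = 7
#' )
#' names(ses$recordings)
generate_session <- function(subject,
                             profiles = default_scenario_profiles(),
                             fs = 500, seed = 1) {
  nm <- vapply(profiles, function(p) p$name, character(1))
  if (anyDuplicated(nm)) abort("Duplicate scenario names in `profiles`.")
  names(profiles) <- nm
  recordings <- list()
  peaks_tbl <- list()
  art_tbl <- list()
  drop_tbl <- list()
  withr::with_seed(seed, {
    for (p in profiles) {
      clean <- clean_ecg_impl(subject, p$duration, fs)
      cont <- scenario_noise_impl(p, p$duration, fs)
      ref <- clean$mv + stats::rnorm(length(clean$mv), 0, p$noise_sd_ref)
      cardiac <- subject$wheel_attenuation * clean$mv
      cardiac <- apply_dropouts(cardiac, cont$dropout_intervals, 0)
      wheel <- cardiac + cont$noise
      recordings[[paste0(p$name, "_reference")]] <-
        new_recording(ref, fs, "reference", p$name, subject$subject_id)
      recordings[[paste0(p$name, "_wheel")]] <-
        new_recording(wheel, fs, "wheel", p$name, subject$subject_id)
      peaks_tbl[[p$name]] <- tibble(
        scenario = p$name, sample_index = clean$truth_peaks
      )
      art_tbl[[p$name]] <- mutate(cont$artifact_intervals, scenario = p$name, .before = 1)
      drop_tbl[[p$name]] <- mutate(cont$dropout_intervals, scenario = p$name, .before = 1)
    }
  })
  list(
    recordings = recordings,
    truth = list(
      peaks = bind_rows(peaks_tbl),
      artifacts = bind_rows(art_tbl),
      dropouts = bind_rows(drop_tbl)
    )
  )
}

#' Draw a cohort of synthetic subjects
#'
#' Subject-level parameters vary the way a healthy driving cohort would:
#' resting heart rate around 72 bpm, modest beat-to-beat variability, and
#' wheel attenuation reflecting different hand/skin contact quality.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @return List of `n` [subject_params()] objects with ids `"S01"`, ...
#' @export
study_subjects <- function(n = 19, seed = 1) {
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      subject_params(
        subject_id = sprintf("S%02d", i),
        base_hr = min(95, max(55, stats::rnorm(1, 72, 8))),
        hr_sd = stats::runif(1, 0.5, 1.5),
        r_amplitude_ref = stats::runif(1, 0.8, 1.2),
        wheel_attenuation = stats::runif(1, 0.25, 0.45)
      )
    })
  })
}
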