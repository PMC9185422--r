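#' Run the full reliability analysis for one subject session
#'
#' Chains the whole method on one synthetic (or imported) session: bandpass
#' both channels per scenario, run the detector bank and STAPLE fusion on
#' each channel, derive heart-rate series, compute the wheel channel's
#' harmonic SNR against the reference heart rate, classify beats with the
#' usability rules (reference exemption applied), and aggregate into usable
#' minutes per scenario.
#'
#' @param session A [generate_session()] result (or a compatible list with
#'   `recordings`).
#' @param bank A [detector_bank()].
#' @param rules A [usability_rules()].
#' @param spec An [snr_spec()].
#' @return Tibble with one row per scenario: `subject_id`, `scenario`,
#'   `usable_minutes`, `total_minutes`, `usable_fraction`, `snr_db`
#'   (recording-level mean), `ref_median_hr`, `n_beats_wheel`.
#' @export
analyze_session <- function(session, bank = detector_bank(),
                            rules = usability_rules(), spec = snr_spec()) {
  recs <- session$recordings
  scen <- unique(vapply(recs, rec_scenario, character(1)))
  purrr::map(scen, function(sc) {
    ref <- recs[[paste0(sc, "_reference")]]
    wheel <- recs[[paste0(sc, "_wheel")]]
    ref_fit <- fuse_detections(ref, bank)
    wheel_fit <- fuse_detections(wheel, bank)
    ref_hr <- hr_series(ref_fit$consensus, rec_fs(ref))
    wheel_hr <- hr_series(wheel_fit$consensus, rec_fs(wheel))
    snr_segments <- snr_db(wheel, ref_hr, spec)
    amps <- beat_amplitudes(wheel, wheel_fit$consensus)
    labels <- classify_beats(wheel_hr, ref_hr,
      amplitudes = if (length(amps) > 1) utils::tail(amps, nrow(wheel_hr)) else NULL,
      rules = rules
    )
    usable <- usable_time(labels, nrow(wheel) / rec_fs(wheel),
      window = rules$window,
      window_reliable_frac = rules$window_reliable_frac
    )
    tibble(
      subject_id = rec_subject(wheel), scenario = sc,
      usable_minutes = usable$usable_minutes,
      total_minutes = usable$total_minutes,
      usable_fraction = usable$usable_fraction,
      snr_db = snr_mean(snr_segments),
      ref_median_hr = stats::median(ref_hr$hr_bpm),
      n_beats_wheel = nrow(wheel_hr) + 1L
    )
  }) |> bind_rows()
}

#' Run the synthetic study end to end
#'
#' Generates `n_subjects` sessions under the default scenario profiles and
#' analyzes each with [analyze_session()], returning per-subject-scenario
#' results ready for [summarize_scenario()] and [summarize_study()].
#'
#' @param n_subjects Number of subjects (the study recorded 19).
#' @param seed Integer seed controlling subjects and sessions.
#' @param profiles Scenario profiles, as [default_scenario_profiles()].
#' @inheritParams analyze_session
#' @param progress Print one line per subject.
#' @return Tibble, `n_subjects * length(profiles)` rows, as from
#'   [analyze_session()].
#' @export
run_study <- function(n_subjects = 19, seed = 1,
                      profiles = default_scenario_profiles(),
                      bank = detector_bank(), rules = usability_rules(),
                      spec = snr_spec(), progress = FALSE) {
  subjects <- study_subjects(n_subjects, seed)
  purrr::imap(subjects, function(sub, i) {
    if (progress) cli::cli_text("Analyzing subject {sub$subject_id} ...")
    session <- generate_session(sub, profiles,
      seed = (seed * 1009L + i * 7919L) %% 2147483629L
    )
    analyze_session(session, bank = bank, rules = rules, spec = spec)
  }) |> bind_rows()
}
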