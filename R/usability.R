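#' Rules for classifying reliable and unreliable beats
#'
#' Three separable rules mark a beat unreliable: (1) the RR interval changes
#' by more than `rri_jump_max` seconds between consecutive beats; (2) the
#' heart rate leaves a tube of half-width `hr_tube_halfwidth` bpm around the
#' median reference heart rate; (3) the beat amplitude exceeds
#' `amp_tube_factor` times the median beat amplitude. On the reference
#' channel the RRI-jump rule is skipped: the chest lead is treated as
#' reliable regardless of that threshold. The 60-100 bpm normal range is
#' used only as a sanity check on the reference median (a warning, not a
#' rejection).
#'
#' @param rri_jump_max Maximum allowed RRI change between consecutive beats,
#'   seconds (default 0.08).
#' @param hr_tube_halfwidth Half-width of the tube around the median
#'   reference HR, bpm.
#' @param amp_tube_factor Amplitude rule multiplier on the median amplitude.
#' @param hr_normal_low,hr_normal_high Normal resting HR range, bpm.
#' @param window Aggregation window, seconds.
#' @param window_reliable_frac Minimum fraction of reliable beats for a
#'   window to count as usable.
#' @return A list of class `usability_rules`.
#' @export
usability_rules <- function(rri_jump_max = 0.08, hr_tube_halfwidth = 10,
                            amp_tube_factor = 3, hr_normal_low = 60,
                            hr_normal_high = 100, window = 60,
                            window_reliable_frac = 0.9) {
  vals <- c(
    rri_jump_max = rri_jump_max, hr_tube_halfwidth = hr_tube_halfwidth,
    amp_tube_factor = amp_tube_factor, window = window,
    window_reliable_frac = window_reliable_frac
  )
  bad <- names(vals)[vals <= 0]
  if (length(bad)) abort(paste0("`", bad[1], "` must be positive."))
  if (hr_normal_low >= hr_normal_high) {
    abort("`hr_normal_low` must be below `hr_normal_high`.")
  }
  structure(
    c(as.list(vals), list(
      hr_normal_low = hr_normal_low, hr_normal_high = hr_normal_high
    )),
    class = "usability_rules"
  )
}

#' Classify each beat of a channel as reliable or unreliable
#'
#' Applies the [usability_rules()] to a channel's heart-rate series. The HR
#' tube is centred on the median of the *reference* series; per-beat
#' amplitudes are optional (the amplitude rule is skipped when absent) and
#' are aligned to the HR series by nearest time when lengths differ.
#'
#' @param channel_hr [hr_series()] tibble of the channel under test.
#' @param ref_hr [hr_series()] tibble of the chest reference.
#' @param amplitudes Optional numeric per-beat amplitudes (mV), or a tibble
#'   with `time_s`, `amp`.
#' @param rules A [usability_rules()].
#' @param is_reference Skip the RRI-jump rule (reference-channel exemption).
#' @return `channel_hr` with added columns `reliable` (logical) and
#'   `rule_fired` (`"none"`, `"rri_jump"`, `"hr_tube"`, `"amplitude"`, or a
#'   `+`-joined combination).
#' @export
#' @examples
#' wheel <- hr_series(new_annotation(cumsum(c(1, 400, 400, 460, 400)), fs = 500))
#' ref <- hr_series(new_annotation(seq(1, 3001, by = 400), fs = 500))
#' classify_beats(wheel, ref)
classify_beats <- function(channel_hr, ref_hr, amplitudes = NULL,
                           rules = usability_rules(), is_reference = FALSE) {
  if (nrow(channel_hr) == 0) {
    return(mutate(channel_hr, reliable = logical(0), rule_fired = character(0)))
  }
  ref_med <- stats::median(ref_hr$hr_bpm)
  if (is.finite(ref_med) &&
    (ref_med < rules$hr_normal_low || ref_med > rules$hr_normal_high)) {
    warn(sprintf(
      "Median reference HR (%.1f bpm) is outside the normal %g-%g bpm range.",
      ref_med, rules$hr_normal_low, rules$hr_normal_high
    ))
  }
  d_rri <- c(0, abs(diff(channel_hr$rri_s)))
  jump <- if (is_reference) rep(FALSE, nrow(channel_hr)) else d_rri > rules$rri_jump_max
  tube <- abs(channel_hr$hr_bpm - ref_med) > rules$hr_tube_halfwidth
  amp_rule <- rep(FALSE, nrow(channel_hr))
  if (!is.null(amplitudes)) {
    amp <- align_amplitudes(amplitudes, channel_hr$time_s)
    amp_rule <- abs(amp) > rules$amp_tube_factor * stats::median(abs(amp), na.rm = TRUE)
    amp_rule[is.na(amp_rule)] <- FALSE
  }
  fired <- purrr::pmap_chr(
    list(jump, tube, amp_rule),
    function(j, t, a) {
      r <- c("rri_jump"[j], "hr_tube"[t], "amplitude"[a])
      if (length(r)) paste(r, collapse = "+") else "none"
    }
  )
  mutate(channel_hr, reliable = !(jump | tube | amp_rule), rule_fired = fired)
}

align_amplitudes <- function(amplitudes, times) {
  if (is.data.frame(amplitudes)) {
    idx <- vapply(times, function(t) which.min(abs(amplitudes$time_s - t)), integer(1))
    return(amplitudes$amp[idx])
  }
  if (length(amplitudes) == length(times)) {
    return(as.numeric(amplitudes))
  }
  # nearest-rank alignment for off-by-k series (e.g., per-peak vs per-pair)
  src <- seq(0, 1, length.out = length(amplitudes))
  dst <- seq(0, 1, length.out = length(times))
  as.numeric(amplitudes)[vapply(dst, function(u) which.min(abs(src - u)), integer(1))]
}

#' Aggregate beat labels into usable minutes
#'
#' Partitions the recording into non-overlapping windows. A window is usable
#' when it contains at least one labelled beat and its fraction of reliable
#' beats reaches `window_reliable_frac`. Usable time is the number of usable
#' windows times the window length.
#'
#' @param labels A [classify_beats()] result (needs `time_s`, `reliable`).
#' @param total_duration Recording duration in seconds.
#' @param window Window length, seconds.
#' @param window_reliable_frac Reliable-beat fraction threshold.
#' @return One-row tibble: `usable_minutes`, `total_minutes`,
#'   `usable_fraction`, `n_windows`, `n_usable_windows`.
#' @export
usable_time <- function(labels, total_duration, window = 60,
                        window_reliable_frac = 0.9) {
  n_win <- max(1L, floor(total_duration / window))
  win_of <- pmin(n_win, floor(labels$time_s / window) + 1L)
  usable <- vapply(seq_len(n_win), function(w) {
    inside <- win_of == w
    sum(inside) > 0 && mean(labels$reliable[inside]) >= window_reliable_frac
  }, logical(1))
  usable_min <- sum(usable) * window / 60
  total_min <- total_duration / 60
  tibble(
    usable_minutes = usable_min, total_minutes = total_min,
    usable_fraction = usable_min / total_min,
    n_windows = n_win, n_usable_windows = sum(usable)
  )
}
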