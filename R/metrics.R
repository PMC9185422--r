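#' SNR estimation settings
#'
#' The wheel channel's signal power is defined as the periodogram power in
#' narrow bands around the cardiac fundamental and its first harmonics, with
#' the fundamental taken from the reference channel's heart rate; everything
#' else inside the 0.5-25 Hz analysis band counts as noise. The harmonic
#' partition (5 harmonics, +/-0.2 Hz) is this package's concrete definition
#' of a harmonic-power SNR for quasi-periodic signals and is configurable.
#'
#' @param harmonics Number of harmonics (>= 1) included as signal.
#' @param band_halfwidth Half-width of each harmonic band, Hz.
#' @param segment Segment length for the periodogram, seconds.
#' @param band_low,band_high Analysis band bounding total power, Hz.
#' @return A list of class `snr_spec`.
#' @export
snr_spec <- function(harmonics = 5, band_halfwidth = 0.2, segment = 60,
                     band_low = 0.5, band_high = 25) {
  if (harmonics < 1) abort("`harmonics` must be at least 1.")
  if (band_halfwidth <= 0) abort("`band_halfwidth` must be positive.")
  structure(
    list(
      harmonics = as.integer(harmonics), band_halfwidth = band_halfwidth,
      segment = segment, band_low = band_low, band_high = band_high
    ),
    class = "snr_spec"
  )
}

# Raw periodogram: power at frequencies freq (Hz). Scaling cancels in the
# signal/noise ratio, so spec.pgram's convention is used as-is.
periodogram <- function(x, fs) {
  pg <- stats::spec.pgram(stats::ts(x, frequency = fs),
    taper = 0, detrend = FALSE, demean = TRUE, fast = FALSE, plot = FALSE
  )
  list(freq = pg$freq, power = pg$spec)
}

#' Harmonic-band SNR of the wheel channel, in dB
#'
#' Splits the recording into non-overlapping segments, estimates each
#' segment's power spectral density by periodogram, and computes
#' `10 * log10(P_signal / P_noise)` where `P_signal` is the power inside
#' `harmonics` bands centred at multiples of the cardiac fundamental and
#' `P_noise` is the remaining 0.5-25 Hz in-band power. The fundamental comes
#' from the reference channel: pass either a fixed frequency in Hz or a
#' reference [hr_series()] tibble, in which case each segment uses the mean
#' reference heart rate over that segment. Segments where the noise power is
#' not positive are clamped to +99 dB with a warning. The recording-level
#' SNR is the arithmetic mean of the per-segment dB values.
#'
#' @param wheel A wheel-channel [new_recording()].
#' @param ref_hr Fundamental frequency in Hz (single number), or a reference
#'   [hr_series()] tibble with columns `time_s`, `hr_bpm`.
#' @param spec An [snr_spec()].
#' @return Tibble with one row per segment: `segment_start_s`, `f0_hz`,
#'   `p_signal`, `p_noise`, `snr_db`; the mean is available through
#'   [snr_mean()] or `mean(out$snr_db)`.
#' @export
snr_db <- function(wheel, ref_hr, spec = snr_spec()) {
  stopifnot(inherits(wheel, "ecg_recording"))
  fs <- rec_fs(wheel)
  n <- nrow(wheel)
  seg_len <- as.integer(round(spec$segment * fs))
  if (seg_len > n) abort("`segment` exceeds the recording length.")
  n_seg <- n %/% seg_len
  out <- purrr::map(seq_len(n_seg), function(s) {
    lo <- (s - 1L) * seg_len + 1L
    seg_start <- (lo - 1) / fs
    x <- wheel$mv[lo:(lo + seg_len - 1L)]
    f0 <- segment_fundamental(ref_hr, seg_start, seg_start + spec$segment)
    if (!is.finite(f0) || f0 <= 0) {
      abort("Fundamental frequency must be positive.")
    }
    pg <- periodogram(x, fs)
    in_band <- pg$freq >= spec$band_low & pg$freq <= spec$band_high
    sig_band <- rep(FALSE, length(pg$freq))
    for (k in seq_len(spec$harmonics)) {
      sig_band <- sig_band |
        abs(pg$freq - k * f0) <= spec$band_halfwidth
    }
    p_sig <- sum(pg$power[in_band & sig_band])
    p_noise <- sum(pg$power[in_band]) - p_sig
    snr <- if (p_noise <= 0) {
      warn("Non-positive noise power; SNR clamped to +99 dB.")
      99
    } else {
      10 * log10(p_sig / p_noise)
    }
    tibble(
      segment_start_s = seg_start, f0_hz = f0,
      p_signal = p_sig, p_noise = p_noise, snr_db = snr
    )
  }) |> bind_rows()
  out
}

segment_fundamental <- function(ref_hr, t0, t1) {
  if (is.numeric(ref_hr) && length(ref_hr) == 1) {
    return(ref_hr)
  }
  stopifnot(is.data.frame(ref_hr), all(c("time_s", "hr_bpm") %in% names(ref_hr)))
  inside <- ref_hr$time_s >= t0 & ref_hr$time_s < t1
  hr <- if (any(inside)) ref_hr$hr_bpm[inside] else ref_hr$hr_bpm
  mean(hr) / 60
}

#' @rdname snr_db
#' @param segments The tibble returned by [snr_db()].
#' @export
snr_mean <- function(segments) mean(segments$snr_db)

#' RR intervals and heart rate from a beat annotation
#'
#' For consecutive R peaks, `rri_s[i] = (peaks[i + 1] - peaks[i]) / fs` and
#' `hr_bpm = 60 / rri_s`; each row is stamped at the time of the second beat
#' of the pair.
#'
#' @param ann A [new_annotation()] with at least two peaks.
#' @param fs Sampling rate; defaults to the annotation's.
#' @return Tibble with `time_s`, `rri_s`, `hr_bpm` (empty if < 2 peaks).
#' @export
#' @examples
#' hr_series(new_annotation(c(1, 501, 1001), fs = 500)) # 60 bpm throughout
hr_series <- function(ann, fs = NULL) {
  fs <- fs %||% ann_fs(ann)
  peaks <- if (inherits(ann, "beat_annotation")) ann_peaks(ann) else as.integer(ann)
  if (length(peaks) < 2) {
    return(tibble(time_s = numeric(0), rri_s = numeric(0), hr_bpm = numeric(0)))
  }
  rri <- diff(peaks) / fs
  tibble(
    time_s = (peaks[-1] - 1) / fs,
    rri_s = rri,
    hr_bpm = 60 / rri
  )
}

#' Per-beat R amplitudes from a recording
#'
#' Amplitude of the bandpassed waveform at each annotated peak, used by the
#' amplitude rule of the usability classifier.
#'
#' @param rec An [new_recording()].
#' @param ann A [new_annotation()] on that recording.
#' @return Numeric vector, one amplitude (mV) per peak.
#' @export
beat_amplitudes <- function(rec, ann) {
  bp <- bandpass_vec(rec$mv, rec_fs(rec), filter_spec(), pad = 2)
  bp[ann_peaks(ann)]
}
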