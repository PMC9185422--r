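#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

SCENARIOS <- c("rest", "city", "highway", "rural")
CHANNELS <- c("reference", "wheel")

#' Construct an ECG recording
#'
#' A recording is a tibble with one row per sample and columns `t_seconds`
#' (time from recording start) and `mv` (amplitude in millivolts), carrying
#' the sampling rate, channel role, driving scenario and subject identifier
#' as attributes. All sample indices used throughout the package are 1-based.
#'
#' @param mv Numeric vector of samples, in millivolts.
#' @param fs Sampling rate in Hz (the study hardware samples at 500 Hz).
#' @param channel One of `"reference"` (chest lead) or `"wheel"`
#'   (steering-wheel electrodes).
#' @param scenario One of `"rest"`, `"city"`, `"highway"`, `"rural"`.
#' @param subject_id Subject identifier string.
#'
#' @return A tibble of class `ecg_recording` with columns `t_seconds`, `mv`.
#' @export
#' @examples
#' rec <- new_recording(sin(2 * pi * 1 * seq(0, 2, by = 1 / 500)), fs = 500)
#' rec_fs(rec)
new_recording <- function(mv, fs = 500, channel = "reference",
                          scenario = "rest", subject_id = "S01") {
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive number.")
  }
  channel <- match.arg(channel, CHANNELS)
  scenario <- match.arg(scenario, SCENARIOS)
  mv <- as.numeric(mv)
  out <- tibble(t_seconds = (seq_along(mv) - 1) / fs, mv = mv)
  structure(out,
    class = c("ecg_recording", class(out)),
    fs = fs, channel = channel, scenario = scenario, subject_id = subject_id
  )
}

#' Recording attribute accessors
#'
#' @param rec An `ecg_recording`.
#' @return The sampling rate (Hz), channel role, scenario tag or subject id.
#' @export
rec_fs <- function(rec) attr(rec, "fs")

#' @rdname rec_fs
#' @export
rec_channel <- function(rec) attr(rec, "channel")

#' @rdname rec_fs
#' @export
rec_scenario <- function(rec) attr(rec, "scenario")

#' @rdname rec_fs
#' @export
rec_subject <- function(rec) attr(rec, "subject_id")

# Rebuild a recording with new samples, keeping metadata.
rec_update <- function(rec, mv) {
  new_recording(mv,
    fs = rec_fs(rec), channel = rec_channel(rec),
    scenario = rec_scenario(rec), subject_id = rec_subject(rec)
  )
}

#' @export
print.ecg_recording <- function(x, ...) {
  cli::cli_text(
    "<ecg_recording> subject {attr(x, 'subject_id')}, {attr(x, 'scenario')}/",
    "{attr(x, 'channel')}, {nrow(x)} samples @ {attr(x, 'fs')} Hz ",
    "({round(nrow(x) / attr(x, 'fs'), 1)} s)"
  )
  NextMethod()
}

#' Construct a beat annotation
#'
#' Ordered R-wave positions as 1-based sample indices with a provenance tag
#' recording where they came from (ground truth, a named detector, or the
#' STAPLE consensus).
#'
#' @param peaks Strictly increasing integer sample indices (1-based).
#' @param fs Sampling rate in Hz of the annotated recording.
#' @param provenance Provenance string: `"truth"`, a detector name, or
#'   `"consensus"`.
#'
#' @return A tibble of class `beat_annotation` with columns `sample_index`
#'   and `provenance`.
#' @export
new_annotation <- function(peaks, fs = 500, provenance = "truth") {
  peaks <- as.integer(round(peaks))
  if (anyNA(peaks)) abort("`peaks` must not contain missing values.")
  if (length(peaks) > 1 && any(diff(peaks) <= 0)) {
    abort("`peaks` must be strictly increasing (duplicates are not allowed).")
  }
  out <- tibble(sample_index = peaks, provenance = provenance[[1]] %||% "truth")
  if (length(peaks) == 0) out$provenance <- character(0)
  structure(out,
    class = c("beat_annotation", class(out)),
    fs = fs, provenance = provenance[[1]]
  )
}

ann_peaks <- function(ann) ann$sample_index

ann_fs <- function(ann) attr(ann, "fs") %||% 500
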