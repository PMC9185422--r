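#' Plot a recording with optional beat annotations
#'
#' @param object An [new_recording()].
#' @param annotation Optional [new_annotation()] overlaid as points.
#' @param window Optional numeric length-2 time window in seconds.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_recording <- function(object, annotation = NULL, window = NULL, ...) {
  dat <- as_tibble(object)
  if (!is.null(window)) {
    dat <- filter(dat, .data$t_seconds >= window[1], .data$t_seconds <= window[2])
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$t_seconds, .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "Time (s)", y = "Amplitude (mV)",
      title = sprintf(
        "%s / %s (%s)", rec_scenario(object), rec_channel(object),
        rec_subject(object)
      )
    )
  if (!is.null(annotation)) {
    ad <- tibble(
      t_seconds = (ann_peaks(annotation) - 1) / rec_fs(object),
      mv = object$mv[ann_peaks(annotation)]
    )
    if (!is.null(window)) {
      ad <- filter(ad, .data$t_seconds >= window[1], .data$t_seconds <= window[2])
    }
    p <- p + ggplot2::geom_point(data = ad, colour = "red", size = 1)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Raincloud-style SNR distribution plot
#'
#' Half-violin density plus jittered per-subject points for each scenario,
#' mirroring the study's SNR distribution figure.
#'
#' @param snr_long Output of [export_snr_distribution()].
#' @return A ggplot object.
#' @export
plot_snr_distribution <- function(snr_long) {
  ggplot2::ggplot(
    snr_long,
    ggplot2::aes(.data$scenario, .data$snr_db, fill = .data$scenario)
  ) +
    ggplot2::geom_violin(alpha = 0.4, colour = NA, scale = "width") +
    ggplot2::geom_jitter(width = 0.08, size = 1, alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 23, size = 2.5) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "SNR (dB)")
}

#' Wheel vs reference heart-rate comparison plot
#'
#' @param wheel_hr,ref_hr [hr_series()] tibbles.
#' @param labels Optional [classify_beats()] output; unreliable wheel beats
#'   are marked.
#' @return A ggplot object.
#' @export
plot_hr_comparison <- function(wheel_hr, ref_hr, labels = NULL) {
  dat <- bind_rows(
    mutate(ref_hr, channel = "reference"),
    mutate(wheel_hr, channel = "wheel")
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$time_s, .data$hr_bpm,
    colour = .data$channel
  )) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "Time (s)", y = "Heart rate (bpm)", colour = NULL)
  if (!is.null(labels)) {
    bad <- filter(labels, !.data$reliable)
    p <- p + ggplot2::geom_point(
      data = bad, colour = "red", size = 1,
      ggplot2::aes(.data$time_s, .data$hr_bpm), inherit.aes = FALSE
    )
  }
  p
}
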