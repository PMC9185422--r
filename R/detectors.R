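# Local maxima of x that exceed `thr`, at least `min_dist` samples apart.
# Greedy by descending height; equal heights resolved to the earliest index.
find_peaks <- function(x, thr = -Inf, min_dist = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] > thr]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(-x[cand], cand)]
  keep <- logical(0)
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= min_dist)) {
      accepted <- c(accepted, i)
    }
  }
  sort(accepted)
}

# Snap each index to the local maximum of `x` within +/- half samples.
snap_to_max <- function(idx, x, half) {
  n <- length(x)
  vapply(idx, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
}

moving_avg <- function(x, w) {
  w <- max(1L, as.integer(w))
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2)) |>
    (\(y) ifelse(is.na(y), 0, y))()
}

too_short <- function(rec, fs, provenance) {
  if (nrow(rec) < 2 * fs) {
    warn(paste0(provenance, ": recording shorter than 2 s; returning no beats."))
    return(TRUE)
  }
  FALSE
}

#' Pan-Tompkins R-peak detector
#'
#' Classical pipeline: 5-15 Hz bandpass, differentiation, squaring, 150 ms
#' moving-window integration, then adaptive dual thresholds over the
#' integrated signal with search-back and a 200 ms refractory period.
#' Detections are refined to the local maximum of the bandpassed signal
#' within +/-50 ms.
#'
#' @param rec An [new_recording()] object (at least 2 s long).
#' @param refractory Minimum inter-beat spacing, seconds.
#' @return A [new_annotation()] with provenance `"pan_tompkins"`.
#' @export
detect_pan_tompkins <- function(rec, refractory = 0.2) {
  fs <- rec_fs(rec)
  if (too_short(rec, fs, "pan_tompkins")) {
    return(new_annotation(integer(0), fs, "pan_tompkins"))
  }
  bp <- bandpass_vec(rec$mv, fs, filter_spec(5, 15, order = 2), pad = 2)
  der <- c(0, diff(bp)) * fs
  sq <- der^2
  w <- as.integer(round(0.15 * fs))
  mwi <- moving_avg(sq, w)
  if (max(mwi) <= 0) return(new_annotation(integer(0), fs, "pan_tompkins"))
  min_dist <- as.integer(round(refractory * fs))
  cand <- find_peaks(mwi, thr = 0, min_dist = min_dist)
  if (!length(cand)) return(new_annotation(integer(0), fs, "pan_tompkins"))

  init <- mwi[1:min(length(mwi), 2 * fs)]
  spki <- max(init)
  npki <- mean(init) / 2
  accepted <- integer(0)
  rr_recent <- numeric(0)
  last <- -Inf
  for (i in cand) {
    h <- mwi[i]
    thr1 <- npki + 0.25 * (spki - npki)
    if (h > thr1 && (i - last) >= min_dist) {
      accepted <- c(accepted, i)
      if (is.finite(last)) rr_recent <- utils::tail(c(rr_recent, i - last), 8)
      last <- i
      spki <- 0.125 * h + 0.875 * spki
    } else {
      npki <- 0.125 * h + 0.875 * npki
      # search-back: long gap since last beat -> accept at the lower threshold
      if (length(rr_recent) >= 2 && is.finite(last) &&
        (i - last) > 1.66 * mean(rr_recent) && h > 0.5 * thr1) {
        accepted <- c(accepted, i)
        rr_recent <- utils::tail(c(rr_recent, i - last), 8)
        last <- i
        spki <- 0.25 * h + 0.75 * spki
      }
    }
  }
  peaks <- unique(snap_to_max(accepted, bp, as.integer(round(0.05 * fs))))
  peaks <- enforce_refractory(peaks, bp, min_dist)
  peaks <- trim_edges(peaks, length(bp), fs)
  new_annotation(peaks, fs, "pan_tompkins")
}

# Filter startup/shutdown transients can masquerade as beats right at the
# recording edges; detections inside the margin are discarded.
trim_edges <- function(peaks, n, fs, margin = 0.3) {
  edge <- as.integer(round(margin * fs))
  peaks[peaks > edge & peaks <= n - edge]
}

# Keep the higher-amplitude peak when two detections violate the refractory.
enforce_refractory <- function(peaks, x, min_dist) {
  peaks <- sort(unique(peaks))
  if (length(peaks) < 2) return(peaks)
  ord <- peaks[order(-x[peaks], peaks)]
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= min_dist)) {
      accepted <- c(accepted, i)
    }
  }
  sort(accepted)
}

#' Squared-derivative R-peak detector
#'
#' First derivative of the band-limited signal, squared and lightly smoothed;
#' the detection threshold adapts as a fraction of the running maximum of the
#' feature signal (1.5 s exponential-decay memory). 200 ms refractory;
#' refinement to the local maximum of the bandpassed signal within +/-50 ms.
#'
#' @inheritParams detect_pan_tompkins
#' @return A [new_annotation()] with provenance `"derivative"`.
#' @export
detect_derivative <- function(rec, refractory = 0.2) {
  fs <- rec_fs(rec)
  if (too_short(rec, fs, "derivative")) {
    return(new_annotation(integer(0), fs, "derivative"))
  }
  bp <- bandpass_vec(rec$mv, fs, filter_spec(0.5, 30, order = 2), pad = 2)
  feat <- moving_avg((c(0, diff(bp)) * fs)^2, round(0.05 * fs))
  if (max(feat) <= 0) return(new_annotation(integer(0), fs, "derivative"))
  # running maximum with exponential forgetting (~1.5 s time constant)
  lambda <- exp(-1 / (1.5 * fs))
  runmax <- numeric(length(feat))
  m <- feat[1]
  for (i in seq_along(feat)) {
    m <- max(feat[i], m * lambda)
    runmax[i] <- m
  }
  min_dist <- as.integer(round(refractory * fs))
  cand <- find_peaks(feat, thr = 0, min_dist = min_dist)
  cand <- cand[feat[cand] > 0.25 * runmax[cand]]
  peaks <- unique(snap_to_max(cand, bp, as.integer(round(0.05 * fs))))
  peaks <- enforce_refractory(peaks, bp, min_dist)
  peaks <- trim_edges(peaks, length(bp), fs)
  new_annotation(peaks, fs, "derivative")
}

#' Shannon-energy envelope R-peak detector
#'
#' Differentiates the band-limited signal, normalizes by its maximum absolute
#' value, computes the Shannon energy `-d^2 log(d^2)`, smooths it into an
#' envelope (120 ms window) and picks envelope peaks with an adaptive
#' threshold and a 200 ms refractory period; refinement as in the other
#' detectors.
#'
#' @inheritParams detect_pan_tompkins
#' @return A [new_annotation()] with provenance `"shannon"`.
#' @export
detect_shannon_energy <- function(rec, refractory = 0.2) {
  fs <- rec_fs(rec)
  if (too_short(rec, fs, "shannon")) {
    return(new_annotation(integer(0), fs, "shannon"))
  }
  bp <- bandpass_vec(rec$mv, fs, filter_spec(3, 20, order = 2), pad = 2)
  d <- c(0, diff(bp))
  mx <- max(abs(d))
  if (mx <= 0) return(new_annotation(integer(0), fs, "shannon"))
  dn <- d / mx
  se <- -dn^2 * log(dn^2 + 1e-12)
  env <- moving_avg(se, round(0.12 * fs))
  lambda <- exp(-1 / (1.5 * fs))
  runmax <- numeric(length(env))
  m <- env[1]
  for (i in seq_along(env)) {
    m <- max(env[i], m * lambda)
    runmax[i] <- m
  }
  min_dist <- as.integer(round(refractory * fs))
  cand <- find_peaks(env, thr = 0, min_dist = min_dist)
  cand <- cand[env[cand] > 0.35 * runmax[cand]]
  peaks <- unique(snap_to_max(cand, bp, as.integer(round(0.05 * fs))))
  peaks <- enforce_refractory(peaks, bp, min_dist)
  peaks <- trim_edges(peaks, length(bp), fs)
  new_annotation(peaks, fs, "shannon")
}

#' Detector bank
#'
#' An ordered, named collection of R-peak detectors used as the independent
#' raters that STAPLE fuses. At least two detectors are required for fusion.
#'
#' @param detectors Named list of functions `f(rec, refractory)` returning a
#'   [new_annotation()].
#' @param refractory Refractory period in seconds passed to every detector.
#' @return A list of class `detector_bank`.
#' @export
detector_bank <- function(detectors = list(
                            pan_tompkins = detect_pan_tompkins,
                            derivative = detect_derivative,
                            shannon = detect_shannon_energy
                          ),
                          refractory = 0.2) {
  if (length(detectors) < 1) abort("`detectors` must not be empty.")
  if (is.null(names(detectors)) || anyDuplicated(names(detectors)) ||
    any(names(detectors) == "")) {
    abort("`detectors` must be a uniquely named list.")
  }
  structure(list(detectors = detectors, refractory = refractory),
    class = "detector_bank"
  )
}

#' Run every detector of a bank on one recording
#'
#' Individual detector failures are caught and reported as warnings; a
#' failing detector contributes an empty annotation rather than aborting the
#' run.
#'
#' @param bank A [detector_bank()].
#' @param rec An [new_recording()] object.
#' @return Named list of [new_annotation()] objects, in bank order.
#' @export
run_bank <- function(bank, rec) {
  stopifnot(inherits(bank, "detector_bank"))
  purrr::imap(bank$detectors, function(f, nm) {
    tryCatch(
      {
        ann <- f(rec, refractory = bank$refractory)
        attr(ann, "provenance") <- nm
        ann$provenance <- rep(nm, nrow(ann))
        ann
      },
      error = function(e) {
        warn(sprintf("Detector '%s' failed (%s); using empty annotation.", nm, conditionMessage(e)))
        new_annotation(integer(0), rec_fs(rec), nm)
      }
    )
  })
}

#' Match a detected annotation against ground truth
#'
#' Greedy one-to-one matching of detections to truth peaks within a time
#' tolerance, yielding precision, recall and F1. Used to score detectors and
#' the STAPLE consensus on synthetic sessions.
#'
#' @param pred,truth [new_annotation()] objects (or integer index vectors).
#' @param fs Sampling rate in Hz (taken from `pred` when it is an annotation).
#' @param tolerance Matching half-width, seconds.
#' @return One-row tibble: `n_pred`, `n_truth`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
annotation_f1 <- function(pred, truth, fs = NULL, tolerance = 0.05) {
  p <- if (inherits(pred, "beat_annotation")) ann_peaks(pred) else as.integer(pred)
  t <- if (inherits(truth, "beat_annotation")) ann_peaks(truth) else as.integer(truth)
  fs <- fs %||% (if (inherits(pred, "beat_annotation")) ann_fs(pred) else 500)
  tol <- tolerance * fs
  tp <- 0L
  used <- logical(length(t))
  for (x in p) {
    j <- which(!used & abs(t - x) <= tol)
    if (length(j)) {
      used[j[which.min(abs(t[j] - x))]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(p) - tp
  fn <- length(t) - tp
  prec <- if (length(p)) tp / length(p) else 0
  rec <- if (length(t)) tp / length(t) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  tibble(
    n_pred = length(p), n_truth = length(t), tp = tp, fp = fp, fn = fn,
    precision = prec, recall = rec, f1 = f1
  )
}
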