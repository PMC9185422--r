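#' Build a candidate-by-detector decision matrix from beat annotations
#'
#' STAPLE fuses per-item binary decisions, but R-peak detectors emit point
#' events. This adapter pools all detector peaks and single-linkage clusters
#' any peaks closer than `tolerance` seconds into candidate events (chains of
#' peaks whose consecutive gaps are all below the tolerance merge). Each
#' candidate's representative index is the median of its member peaks, and
#' `votes[c, d] = 1` when detector `d` contributed a peak to candidate `c`.
#'
#' @param annotations List of [new_annotation()] objects (>= 2 for fusion).
#' @param fs Sampling rate in Hz; defaults to the first annotation's.
#' @param tolerance Clustering half-width in seconds (50 ms by default,
#'   about half a QRS width).
#'
#' @return A list of class `decision_matrix` with `candidates` (integer
#'   indices), `votes` (candidates x detectors 0/1 matrix, detector-named
#'   columns), `fs` and `tolerance`.
#' @export
build_decision_matrix <- function(annotations, fs = NULL, tolerance = 0.05) {
  if (length(annotations) < 2) {
    abort("At least two annotations are required for fusion.")
  }
  nms <- names(annotations) %||%
    vapply(annotations, function(a) attr(a, "provenance") %||% "detector", character(1))
  if (anyDuplicated(nms)) nms <- make.unique(nms)
  names(annotations) <- nms
  fs <- fs %||% ann_fs(annotations[[1]])
  pool <- purrr::imap(annotations, function(a, i) {
    tibble(sample_index = ann_peaks(a), detector = i)
  }) |> bind_rows()
  if (nrow(pool) == 0) {
    warn("All annotations are empty; returning an empty decision matrix.")
    return(structure(
      list(
        candidates = integer(0),
        votes = matrix(0L, 0, length(annotations), dimnames = list(NULL, nms)),
        fs = fs, tolerance = tolerance
      ),
      class = "decision_matrix"
    ))
  }
  pool <- arrange(pool, .data$sample_index)
  gap <- tolerance * fs
  cluster <- cumsum(c(1L, as.integer(diff(pool$sample_index) >= gap)))
  pool$cluster <- cluster
  cands <- pool |>
    group_by(.data$cluster) |>
    summarise(rep = as.integer(round(stats::median(.data$sample_index))), .groups = "drop")
  votes <- matrix(0L, nrow(cands), length(annotations),
    dimnames = list(NULL, nms)
  )
  hit <- distinct(pool, .data$cluster, .data$detector)
  votes[cbind(
    match(hit$cluster, cands$cluster),
    match(hit$detector, nms)
  )] <- 1L
  ord <- order(cands$rep)
  structure(
    list(
      candidates = cands$rep[ord], votes = votes[ord, , drop = FALSE],
      fs = fs, tolerance = tolerance
    ),
    class = "decision_matrix"
  )
}

staple_loglik <- function(votes, p, q, prior) {
  lp_true <- votes %*% log(p) + (1 - votes) %*% log(1 - p)
  lp_false <- votes %*% log(1 - q) + (1 - votes) %*% log(q)
  sum(log(prior * exp(lp_true) + (1 - prior) * exp(lp_false)))
}

#' STAPLE expectation-maximization over a decision matrix
#'
#' Simultaneous truth and performance level estimation for binary raters:
#' each detector `d` is modelled by a sensitivity `p[d]` (probability of
#' voting for a true beat) and a specificity `q[d]` (probability of staying
#' silent on a non-beat candidate). The E-step computes each candidate's
#' posterior probability of being a true beat under the current `(p, q)` and
#' prior; the M-step re-estimates `(p, q)` from the posteriors. Iteration
#' stops when the largest absolute change in `(p, q)` falls below `tol` or
#' after `max_iter` rounds. The algorithm is deterministic. Candidates with
#' posterior >= 0.5 form the consensus (weighted majority voting).
#'
#' @param matrix A [build_decision_matrix()] result.
#' @param prior Prior probability that a candidate is a true beat;
#'   `"auto"` uses the fraction of candidates carrying at least half the
#'   votes, clamped to \[0.05, 0.95\].
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on `(p, q)`.
#'
#' @return A list of class `staple_fit`: `consensus` ([new_annotation()],
#'   provenance `"consensus"`), `p`, `q` (named per detector), `posteriors`,
#'   `candidates`, `votes`, `prior`, `loglik` (per-iteration trace),
#'   `iterations`, `converged`.
#' @export
staple_em <- function(matrix, prior = "auto", max_iter = 100, tol = 1e-6) {
  stopifnot(inherits(matrix, "decision_matrix"))
  votes <- matrix$votes
  if (nrow(votes) == 0) abort("Decision matrix is empty; nothing to fuse.")
  nd <- ncol(votes)
  if (identical(prior, "auto")) {
    prior <- mean(rowSums(votes) >= nd / 2)
    prior <- min(0.95, max(0.05, prior))
  }
  if (prior <= 0 || prior >= 1) abort("`prior` must lie strictly in (0, 1).")
  eps <- 1e-6
  p <- rep(0.9, nd)
  q <- rep(0.9, nd)
  ll <- numeric(0)
  converged <- FALSE
  iter <- 0L
  post <- rep(prior, nrow(votes))
  for (iter in seq_len(max_iter)) {
    # E-step
    lp_true <- votes %*% log(p) + (1 - votes) %*% log(1 - p)
    lp_false <- votes %*% log(1 - q) + (1 - votes) %*% log(q)
    a <- prior * exp(lp_true)
    b <- (1 - prior) * exp(lp_false)
    post <- as.numeric(a / (a + b))
    ll <- c(ll, sum(log(a + b)))
    # M-step
    p_new <- as.numeric(crossprod(votes, post) / sum(post))
    q_new <- as.numeric(crossprod(1 - votes, 1 - post) / sum(1 - post))
    p_new <- pmin(1 - eps, pmax(eps, p_new))
    q_new <- pmin(1 - eps, pmax(eps, q_new))
    delta <- max(abs(c(p_new - p, q_new - q)))
    p <- p_new
    q <- q_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  keep <- post >= 0.5
  consensus <- new_annotation(matrix$candidates[keep], matrix$fs, "consensus")
  structure(
    list(
      consensus = consensus, p = stats::setNames(p, colnames(votes)),
      q = stats::setNames(q, colnames(votes)), posteriors = post,
      candidates = matrix$candidates, votes = votes, prior = prior,
      loglik = ll, iterations = iter, converged = converged, fs = matrix$fs
    ),
    class = "staple_fit"
  )
}

#' @export
print.staple_fit <- function(x, ...) {
  cli::cli_text(
    "<staple_fit> {length(x$candidates)} candidates, ",
    "{nrow(x$consensus)} consensus beats, {x$iterations} EM iterations ",
    "({if (x$converged) 'converged' else 'not converged'})"
  )
  print(tidy(x))
  invisible(x)
}

#' Tidy a STAPLE fit
#'
#' One row per detector with its estimated sensitivity and specificity.
#'
#' @param x A `staple_fit`.
#' @param ... Unused.
#' @return Tibble with `detector`, `sensitivity`, `specificity`.
#' @export
tidy.staple_fit <- function(x, ...) {
  tibble(
    detector = names(x$p),
    sensitivity = unname(x$p),
    specificity = unname(x$q)
  )
}

#' Glance at a STAPLE fit
#'
#' @param x A `staple_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n_candidates`, `n_consensus`, `prior`,
#'   `iterations`, `converged`, `loglik`.
#' @export
glance.staple_fit <- function(x, ...) {
  tibble(
    n_candidates = length(x$candidates),
    n_consensus = nrow(x$consensus),
    prior = x$prior,
    iterations = x$iterations,
    converged = x$converged,
    loglik = utils::tail(x$loglik, 1)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Snap consensus beats to the bandpassed waveform
#'
#' Each consensus index is moved to the local maximum of the 0.5-25 Hz
#' bandpassed recording within +/-50 ms. When two candidates snap to the
#' same maximum, the one with the higher posterior survives.
#'
#' @param fit A [staple_em()] result.
#' @param rec The recording the annotations were produced from.
#' @param halfwidth Snapping half-width, seconds.
#' @return A [new_annotation()] with provenance `"consensus"`.
#' @export
consensus_refine <- function(fit, rec, halfwidth = 0.05) {
  stopifnot(inherits(fit, "staple_fit"), inherits(rec, "ecg_recording"))
  idx <- ann_peaks(fit$consensus)
  if (!length(idx)) return(new_annotation(integer(0), rec_fs(rec), "consensus"))
  post <- fit$posteriors[fit$candidates %in% idx]
  bp <- bandpass_vec(rec$mv, rec_fs(rec), filter_spec(), pad = 2)
  snapped <- snap_to_max(idx, bp, as.integer(round(halfwidth * rec_fs(rec))))
  keep <- tibble(sample_index = snapped, posterior = post) |>
    group_by(.data$sample_index) |>
    slice_max(.data$posterior, n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(.data$sample_index)
  new_annotation(keep$sample_index, rec_fs(rec), "consensus")
}

#' Detect, fuse and refine in one call
#'
#' Convenience wrapper chaining [run_bank()], [build_decision_matrix()],
#' [staple_em()] and [consensus_refine()] on one recording.
#'
#' @inheritParams run_bank
#' @inheritParams build_decision_matrix
#' @inheritParams staple_em
#' @param refine Snap the consensus to the bandpassed waveform.
#' @return A `staple_fit` whose `consensus` is refined when `refine = TRUE`.
#' @export
fuse_detections <- function(rec, bank = detector_bank(), tolerance = 0.05,
                            prior = "auto", refine = TRUE) {
  anns <- run_bank(bank, rec)
  mat <- build_decision_matrix(anns, fs = rec_fs(rec), tolerance = tolerance)
  fit <- staple_em(mat, prior = prior)
  if (refine && nrow(fit$consensus) > 0) {
    fit$consensus <- consensus_refine(fit, rec)
  }
  fit
}
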