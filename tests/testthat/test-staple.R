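test_that("unanimous annotations produce an all-ones decision matrix", {
  peaks <- c(100L, 600L, 1100L)
  anns <- list(
    a = new_annotation(peaks, 500, "a"),
    b = new_annotation(peaks, 500, "b"),
    c = new_annotation(peaks, 500, "c")
  )
  m <- build_decision_matrix(anns, fs = 500)
  expect_identical(m$candidates, peaks)
  expect_true(all(m$votes == 1L))
})

test_that("peaks within tolerance merge; outliers become extra candidates", {
  # brute-force clustering by hand: offsets of 10 ms merge at 50 ms tolerance
  anns <- list(
    a = new_annotation(c(100L, 600L, 1100L), 500, "a"),
    b = new_annotation(c(105L, 605L, 1105L), 500, "b")
  )
  m <- build_decision_matrix(anns, fs = 500, tolerance = 0.05)
  expect_identical(nrow(m$votes), 3L)
  expect_true(all(rowSums(m$votes) == 2))
  expect_identical(m$candidates, c(102L, 602L, 1102L)) # median of each pair

  # a spurious extra peak 300 ms away gets its own single-vote candidate
  anns$b <- new_annotation(c(105L, 455L, 605L, 1105L), 500, "b")
  m2 <- build_decision_matrix(anns, fs = 500, tolerance = 0.05)
  expect_identical(nrow(m2$votes), 4L)
  lone <- which(m2$candidates == 455L)
  expect_identical(unname(rowSums(m2$votes)[lone]), 1)
})

test_that("empty annotations give an empty matrix with a warning", {
  anns <- list(a = new_annotation(integer(0)), b = new_annotation(integer(0)))
  expect_warning(m <- build_decision_matrix(anns, fs = 500), "empty")
  expect_identical(length(m$candidates), 0L)
  expect_error(staple_em(m), "empty")
  expect_error(build_decision_matrix(anns[1]), "two")
})

test_that("unanimous votes are a fixed point with full consensus", {
  votes <- matrix(1L, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- structure(
    list(
      candidates = as.integer(1:10 * 500), votes = votes,
      fs = 500, tolerance = 0.05
    ),
    class = "decision_matrix"
  )
  fit <- staple_em(m, prior = 0.9)
  expect_true(all(fit$posteriors >= 0.5))
  expect_identical(nrow(fit$consensus), 10L)
  expect_true(all(fit$p >= 1 - 1e-5))
})

test_that("EM recovers known detector operating points", {
  # n large enough that binomial noise (sd ~ 0.02) sits well inside +/-0.05
  sim <- make_vote_matrix(
    p = c(0.95, 0.80, 0.60), q = c(0.99, 0.95, 0.90),
    n = 2000, prevalence = 0.3, seed = 42
  )
  fit <- staple_em(sim$matrix)
  expect_true(all(abs(fit$p - c(0.95, 0.80, 0.60)) <= 0.05))
  expect_true(all(abs(fit$q - c(0.99, 0.95, 0.90)) <= 0.05))
  expect_true(fit$converged)
  # the EM objective never decreases
  expect_true(all(diff(fit$loglik) >= -1e-9))
})

test_that("a 2x2 toy matrix ranks the unanimously voted candidate higher", {
  m <- structure(
    list(
      candidates = c(500L, 1000L),
      votes = matrix(c(1L, 1L, 1L, 0L), 2, 2, byrow = TRUE,
        dimnames = list(NULL, c("a", "b"))
      ),
      fs = 500, tolerance = 0.05
    ),
    class = "decision_matrix"
  )
  fit <- staple_em(m, prior = 0.5, max_iter = 2)
  expect_gte(fit$posteriors[1], fit$posteriors[2])
})

test_that("detector order only permutes the performance estimates", {
  sim <- make_vote_matrix(c(0.95, 0.8, 0.6), c(0.99, 0.95, 0.9), n = 300, seed = 7)
  fit <- staple_em(sim$matrix)
  perm <- c(3, 1, 2)
  m2 <- sim$matrix
  m2$votes <- m2$votes[, perm]
  fit2 <- staple_em(m2)
  expect_equal(unname(fit2$p), unname(fit$p[perm]), tolerance = 1e-8)
  expect_equal(unname(fit2$q), unname(fit$q[perm]), tolerance = 1e-8)
  expect_identical(fit2$consensus$sample_index, fit$consensus$sample_index)
})

test_that("raising the posterior threshold never adds consensus peaks", {
  sim <- make_vote_matrix(c(0.9, 0.8, 0.7), c(0.95, 0.9, 0.85), n = 300, seed = 9)
  fit <- staple_em(sim$matrix)
  sets <- lapply(c(0.3, 0.5, 0.7, 0.9), function(thr) {
    sim$matrix$candidates[fit$posteriors >= thr]
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("degenerate unanimous columns stay clamped inside (0, 1)", {
  votes <- cbind(a = rep(1L, 20), b = rep(1L, 20), c = rep(0L, 20))
  m <- structure(
    list(
      candidates = as.integer(1:20 * 400), votes = votes,
      fs = 500, tolerance = 0.05
    ),
    class = "decision_matrix"
  )
  fit <- staple_em(m, prior = 0.5)
  expect_true(all(fit$p > 0 & fit$p < 1))
  expect_true(all(fit$q > 0 & fit$q < 1))
})

test_that("consensus refinement snaps onto nearby R maxima", {
  fix <- make_clean_rec(base_hr = 70, hr_sd = 1, duration = 30, seed = 12)
  fit <- fuse_detections(fix$rec, refine = FALSE)
  refined <- consensus_refine(fit, fix$rec)
  # snapping moves clean-signal consensus peaks at most 2 samples
  common <- min(nrow(fit$consensus), nrow(refined))
  expect_lte(max(abs(refined$sample_index[1:common] -
    fit$consensus$sample_index[1:common])), 2)
  expect_true(all(diff(refined$sample_index) > 0))
  # empty consensus passes through
  empty_fit <- fit
  empty_fit$consensus <- new_annotation(integer(0), 500, "consensus")
  expect_identical(nrow(consensus_refine(empty_fit, fix$rec)), 0L)
})

test_that("tidy and glance expose the fit in broom shape", {
  sim <- make_vote_matrix(c(0.95, 0.8, 0.6), c(0.99, 0.95, 0.9), n = 200, seed = 3)
  fit <- staple_em(sim$matrix)
  td <- tidy(fit)
  expect_named(td, c("detector", "sensitivity", "specificity"))
  expect_identical(nrow(td), 3L)
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
})
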