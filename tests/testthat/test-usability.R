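# Build an hr_series tibble directly from a vector of RR intervals.
hr_from_rri <- function(rri, t0 = 1) {
  tibble::tibble(
    time_s = t0 + cumsum(rri),
    rri_s = rri,
    hr_bpm = 60 / rri
  )
}

test_that("an RRI change above 0.08 s flags the affected beats", {
  wheel <- hr_from_rri(c(0.8, 0.8, 0.92, 0.8))
  ref <- hr_from_rri(rep(0.8, 60))
  lab <- classify_beats(wheel, ref)
  expect_false(lab$reliable[3]) # 0.12 s jump into this beat
  expect_true(lab$reliable[1])
  expect_true(lab$reliable[2])
  expect_true(grepl("rri_jump", lab$rule_fired[3]))
})

test_that("the reference channel is exempt from the RRI-jump rule", {
  ref_hr <- hr_from_rri(c(0.8, 0.8, 0.92, 0.8))
  lab <- classify_beats(ref_hr, ref_hr, is_reference = TRUE)
  expect_true(all(lab$reliable))
  expect_true(all(lab$rule_fired == "none"))
})

test_that("no rule fires on a steady, in-tube, uniform-amplitude series", {
  wheel <- hr_from_rri(rep(0.8, 100))
  ref <- hr_from_rri(rep(0.8, 100))
  lab <- classify_beats(wheel, ref, amplitudes = rep(0.5, 100))
  expect_true(all(lab$reliable))
})

test_that("the HR tube and amplitude rules fire independently", {
  ref <- hr_from_rri(rep(0.8, 100)) # median 75 bpm
  wheel <- hr_from_rri(rep(c(0.8, 0.65), 20)) # 92 bpm beats leave the tube
  lab <- classify_beats(wheel, ref, rules = usability_rules(rri_jump_max = 1))
  expect_true(any(grepl("hr_tube", lab$rule_fired)))

  amps <- c(rep(0.5, 50), 5, rep(0.5, 9))
  wheel2 <- hr_from_rri(rep(0.8, 60))
  lab2 <- classify_beats(wheel2, ref, amplitudes = amps)
  expect_false(lab2$reliable[51])
  expect_identical(lab2$rule_fired[51], "amplitude")
})

test_that("an out-of-range reference median only warns", {
  ref <- hr_from_rri(rep(1.2, 50)) # 50 bpm
  wheel <- hr_from_rri(rep(1.2, 50))
  expect_warning(lab <- classify_beats(wheel, ref), "normal")
  expect_true(all(lab$reliable))
})

test_that("usable time counts windows by their reliable-beat fraction", {
  # hand-constructed 5-window label set with exactly 3 windows above 0.9
  labels <- tibble::tibble(
    time_s = rep(0:4 * 60, each = 10) + rep(seq(2, 56, length.out = 10), 5),
    reliable = c(
      rep(TRUE, 10), # window 1: 1.0 usable
      c(rep(TRUE, 9), FALSE), # window 2: 0.9  usable
      c(rep(TRUE, 8), FALSE, FALSE), # window 3: 0.8  not
      rep(TRUE, 10), # window 4: usable
      rep(FALSE, 10) # window 5: not
    )
  )
  out <- usable_time(labels, total_duration = 300)
  expect_identical(out$n_usable_windows, 3L)
  expect_equal(out$usable_minutes, 3)
  expect_equal(out$usable_fraction, 3 / 5)
})

test_that("fully reliable and alternating label patterns bound the range", {
  t <- seq(1, 899, by = 0.8)
  all_good <- tibble::tibble(time_s = t, reliable = TRUE)
  out <- usable_time(all_good, 900)
  expect_equal(out$usable_minutes, 15)
  expect_equal(out$usable_fraction, 1)

  alternating <- tibble::tibble(time_s = t, reliable = rep(c(TRUE, FALSE), length.out = length(t)))
  expect_equal(usable_time(alternating, 900)$usable_minutes, 0)
})

test_that("usable minutes are monotone in the RRI-jump threshold", {
  fix <- make_noisy_rec(duration = 300, seed = 17)
  wf <- fuse_detections(fix$rec)
  rf <- fuse_detections(fix$ref)
  wh <- hr_series(wf$consensus, 500)
  rh <- hr_series(rf$consensus, 500)
  mins <- vapply(c(0.02, 0.05, 0.08, 0.2, 1), function(jump) {
    lab <- classify_beats(wh, rh, rules = usability_rules(rri_jump_max = jump))
    usable_time(lab, 300)$usable_minutes
  }, numeric(1))
  expect_true(all(diff(mins) >= 0))
})
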