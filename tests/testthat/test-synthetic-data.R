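test_that("zero-variance heart rate gives exactly 1.0 s beat spacing", {
  fix <- make_clean_rec(base_hr = 60, hr_sd = 0, duration = 60, seed = 3)
  expect_true(length(fix$truth) %in% c(60L, 61L))
  expect_true(all(diff(fix$truth) == 500L))
})

test_that("generated heart rate matches the requested base rate", {
  # oracle: arithmetic on the generator's own interval draws (truth peaks)
  for (seed in 1:5) {
    fix <- make_clean_rec(base_hr = 60, hr_sd = 2, duration = 60, seed = seed)
    hr <- 60 / (diff(fix$truth) / 500)
    expect_lt(abs(mean(hr) - 60), 2)
  }
})

test_that("generation is deterministic in the seed", {
  a <- generate_clean_ecg(subject_params(), 20, 500, seed = 11)
  b <- generate_clean_ecg(subject_params(), 20, 500, seed = 11)
  expect_identical(a, b)
  s1 <- generate_session(subject_params(), default_scenario_profiles()["rest"], seed = 5)
  s2 <- generate_session(subject_params(), default_scenario_profiles()["rest"], seed = 5)
  expect_identical(s1$recordings$rest_wheel$mv, s2$recordings$rest_wheel$mv)
  expect_identical(s1$truth, s2$truth)
})

test_that("invalid generator parameters are rejected by name", {
  expect_error(generate_clean_ecg(subject_params(), -1, 500), "duration")
  expect_error(generate_clean_ecg(subject_params(), 10, -5), "fs")
  expect_error(subject_params(base_hr = 30), "base_hr")
  expect_error(subject_params(wheel_attenuation = 0), "wheel_attenuation")
})

test_that("degenerate profile produces identically zero noise", {
  prof <- scenario_profile("rest", 60,
    dropout_rate = 0, artifact_rate = 0,
    noise_sd_wheel = 0, wander_amplitude = 0
  )
  out <- generate_scenario_noise(prof, 60, 500, seed = 1)
  expect_identical(out$noise, rep(0, 30000))
  expect_identical(nrow(out$artifact_intervals), 0L)
  expect_identical(nrow(out$dropout_intervals), 0L)
})

test_that("dropout counts follow the Poisson arrival rate", {
  # oracle: Poisson(30) for 2 events/min over 15 min; mean of 20 seeds
  prof <- scenario_profile("city", 900, dropout_rate = 2, dropout_mean_len = 1)
  counts <- vapply(1:20, function(s) {
    nrow(generate_scenario_noise(prof, 900, 100, seed = s)$dropout_intervals)
  }, integer(1))
  expect_lt(abs(mean(counts) - 30), 3 * sqrt(30 / 20))
})

test_that("intervals stay inside the recording and are half-open", {
  prof <- scenario_profile("city", 30,
    dropout_rate = 20, dropout_mean_len = 3,
    artifact_rate = 20
  )
  out <- generate_scenario_noise(prof, 30, 500, seed = 9)
  for (tbl in list(out$artifact_intervals, out$dropout_intervals)) {
    expect_true(all(tbl$start_sample >= 1))
    expect_true(all(tbl$end_sample <= 30 * 500 + 1))
    expect_true(all(tbl$end_sample > tbl$start_sample))
  }
})

test_that("session honours channel linearity and shared truth", {
  sub <- subject_params(wheel_attenuation = 0.4)
  quiet <- scenario_profile("rest", 30,
    dropout_rate = 0, artifact_rate = 0,
    noise_sd_wheel = 0, noise_sd_ref = 0, wander_amplitude = 0
  )
  ses <- generate_session(sub, list(rest = quiet), seed = 2)
  ref <- ses$recordings$rest_reference
  wheel <- ses$recordings$rest_wheel
  expect_equal(wheel$mv, 0.4 * ref$mv, tolerance = 1e-12)
  expect_identical(nrow(ref), nrow(wheel))
  expect_identical(nrow(ref), 30L * 500L)
})

test_that("default study layout matches the experimental design", {
  profs <- default_scenario_profiles()
  expect_identical(
    vapply(profs, function(p) p$duration, numeric(1)),
    c(rest = 300, city = 900, highway = 900, rural = 900)
  )
  expect_error(
    generate_session(
      subject_params(),
      list(rest = profs$rest, rest2 = profs$rest)
    ),
    "Duplicate"
  )
})

test_that("wheel SNR decreases as broadband noise grows", {
  # oracle: harmonic-band SNR recomputed at three noise levels
  snrs <- vapply(c(0.02, 0.08, 0.3), function(ns) {
    sub <- subject_params(base_hr = 60, hr_sd = 0)
    prof <- scenario_profile("rest", 60,
      dropout_rate = 0, artifact_rate = 0,
      noise_sd_wheel = ns, wander_amplitude = 0
    )
    ses <- generate_session(sub, list(rest = prof), seed = 31)
    snr_mean(snr_db(ses$recordings$rest_wheel, 1))
  }, numeric(1))
  expect_true(all(diff(snrs) < 0))
})
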