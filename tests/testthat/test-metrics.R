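test_that("equal in-band signal and noise power gives 0 dB", {
  fs <- 500
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  # fundamental at 1 Hz plus an equal-power off-harmonic tone at 7.3 Hz
  x <- sin(2 * pi * 1 * t) + sin(2 * pi * 7.3 * t)
  rec <- new_recording(x, fs, channel = "wheel")
  out <- snr_db(rec, 1)
  expect_lt(abs(out$snr_db), 0.5)
})

test_that("scaling the noise by 10 shifts the SNR by -20 dB", {
  fs <- 500
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  withr::with_seed(21, noise <- stats::rnorm(length(t), 0, 0.2))
  sig <- sin(2 * pi * 1.2 * t)
  a <- snr_mean(snr_db(new_recording(sig + noise, fs, channel = "wheel"), 1.2))
  b <- snr_mean(snr_db(new_recording(sig + 10 * noise, fs, channel = "wheel"), 1.2))
  expect_lt(abs((a - b) - 20), 1)
})

test_that("SNR is invariant to global amplitude rescaling", {
  fix <- make_noisy_rec(seed = 2)
  a <- snr_db(fix$rec, 70 / 60)
  doubled <- new_recording(7 * fix$rec$mv, 500, channel = "wheel")
  b <- snr_db(doubled, 70 / 60)
  expect_lt(max(abs(a$snr_db - b$snr_db)), 1e-9)
})

test_that("a noise-free fundamental clamps at +99 dB", {
  fs <- 500
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  rec <- new_recording(sin(2 * pi * 1 * t), fs, channel = "wheel")
  expect_warning(out <- snr_db(rec, 1, snr_spec(harmonics = 5)), "clamped")
  expect_true(any(out$snr_db == 99))
})

test_that("the recording-level SNR is the mean of segment values", {
  fix <- make_noisy_rec(duration = 180, seed = 6)
  out <- snr_db(fix$rec, 70 / 60)
  expect_identical(nrow(out), 3L)
  expect_equal(snr_mean(out), mean(out$snr_db))
})

test_that("segments use the reference heart rate as fundamental", {
  fs <- 500
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  rec <- new_recording(sin(2 * pi * 1.5 * t), fs, channel = "wheel")
  ref_hr <- tibble::tibble(time_s = seq(1, 59, by = 1), hr_bpm = 90)
  out <- suppressWarnings(snr_db(rec, ref_hr)) # noise-free tone clamps
  expect_equal(out$f0_hz, 1.5)
  expect_error(snr_db(rec, 1, snr_spec(segment = 120)), "length")
})

test_that("RR intervals and heart rate obey HR = 60/RRI", {
  ann <- new_annotation(c(1L, 501L, 1001L), 500)
  hs <- hr_series(ann)
  expect_equal(hs$rri_s, c(1, 1))
  expect_equal(hs$hr_bpm, c(60, 60))
  expect_equal(hr_series(new_annotation(c(1L, 251L), 500))$hr_bpm, 120)

  # property: hr * rri == 60 exactly, under random strictly increasing peaks
  withr::with_seed(5, {
    for (i in 1:20) {
      peaks <- cumsum(sample(50:700, 50, replace = TRUE))
      hs <- hr_series(new_annotation(peaks, 500))
      expect_lt(max(abs(hs$hr_bpm * hs$rri_s - 60)), 1e-12)
    }
  })
})

test_that("hr_series is equivariant to index translation and guards inputs", {
  peaks <- cumsum(c(100L, rep(400L, 20)))
  a <- hr_series(new_annotation(peaks, 500))
  b <- hr_series(new_annotation(peaks + 777L, 500))
  expect_equal(b$rri_s, a$rri_s)
  expect_equal(b$time_s - a$time_s, rep(777 / 500, nrow(a)))
  expect_identical(nrow(hr_series(new_annotation(100L, 500))), 0L)
})
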