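# Shared fixtures, built in code at test time.

make_clean_rec <- function(base_hr = 60, hr_sd = 0, duration = 60, fs = 500,
                           seed = 1, channel = "reference") {
  sub <- subject_params(base_hr = base_hr, hr_sd = hr_sd)
  sim <- generate_clean_ecg(sub, duration, fs, seed = seed)
  list(
    rec = new_recording(sim$mv, fs, channel = channel),
    truth = sim$truth_peaks,
    subject = sub
  )
}

# A wheel-like contaminated recording with known truth.
make_noisy_rec <- function(base_hr = 70, duration = 60, fs = 500, seed = 1,
                           noise_sd = 0.05, artifact_rate = 2,
                           dropout_rate = 0.5) {
  sub <- subject_params(base_hr = base_hr, hr_sd = 1, wheel_attenuation = 0.35)
  prof <- scenario_profile("city", duration,
    dropout_rate = dropout_rate, dropout_mean_len = 2,
    artifact_rate = artifact_rate, noise_sd_wheel = noise_sd,
    noise_sd_ref = 0.01, wander_amplitude = 0.2, wander_freq = 0.3
  )
  ses <- generate_session(sub, list(city = prof), fs = fs, seed = seed)
  list(
    rec = ses$recordings$city_wheel,
    ref = ses$recordings$city_reference,
    truth = ses$truth$peaks$sample_index
  )
}

# Simulated decision matrix with known per-detector operating points.
make_vote_matrix <- function(p, q, n = 500, prevalence = 0.3, seed = 42,
                             fs = 500) {
  withr::with_seed(seed, {
    z <- stats::rbinom(n, 1, prevalence)
    votes <- vapply(seq_along(p), function(d) {
      ifelse(z == 1,
        stats::rbinom(n, 1, p[d]),
        stats::rbinom(n, 1, 1 - q[d])
      )
    }, integer(n))
    colnames(votes) <- paste0("det", seq_along(p))
    list(
      matrix = structure(
        list(
          candidates = as.integer(seq_len(n) * fs), votes = votes,
          fs = fs, tolerance = 0.05
        ),
        class = "decision_matrix"
      ),
      truth = z
    )
  })
}
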