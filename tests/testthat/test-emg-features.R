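make_env <- function(mat, fs = 500, normalized = TRUE) {
  structure(list(fs = fs, envelope = mat, normalized = normalized),
    class = "emg_envelope"
  )
}

two_chan <- function(x, y = x) {
  m <- cbind(ES_L = x, ES_R = y)
  m
}

test_that("the preprocessing chain rejects DC and passes the band center", {
  fs <- 2148
  t <- seq(0, 10, by = 1 / fs)
  # pure DC in -> essentially zero envelope out
  rec_dc <- emg_recording(two_chan(rep(2.5, length(t))), fs = fs)
  env_dc <- preprocess_emg(rec_dc)$envelope
  expect_lt(max(env_dc), 2.5 * 1e-6)
  # 100 Hz unit sinusoid -> steady-state envelope = mean of rectified sine
  rec_100 <- emg_recording(two_chan(sin(2 * pi * 100 * t)), fs = fs)
  env_100 <- preprocess_emg(rec_100)$envelope
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  expect_equal(mean(env_100[mid, "ES_L"]), 2 / pi, tolerance = 0.02)
  # 5 Hz sinusoid sits below the 20 Hz edge: strongly attenuated
  rec_5 <- emg_recording(two_chan(sin(2 * pi * 5 * t)), fs = fs)
  env_5 <- preprocess_emg(rec_5)$envelope
  expect_lt(mean(env_5[mid, "ES_L"]), 0.1 * mean(env_100[mid, "ES_L"]))
})

test_that("too-short recordings are rejected", {
  rec <- emg_recording(two_chan(stats::rnorm(300)), fs = 2148)
  expect_error(preprocess_emg(rec), "too short")
})

test_that("MVC reference is the envelope maximum and normalization is exact", {
  cohort <- tiny_cohort()
  p <- cohort$participants[[1]]
  ref <- mvc_reference(p$mvc)
  env <- preprocess_emg(p$mvc)$envelope
  expect_equal(unname(ref), unname(apply(env, 2, max)))
  # normalizing the MVC's own envelope puts its maximum at exactly 1
  norm <- normalize_envelope(preprocess_emg(p$mvc), ref)
  expect_equal(unname(apply(norm$envelope, 2, max)), c(1, 1))
  expect_error(mvc_reference(p$trials[["none"]]$emg), "role")
})

test_that("the synthetic MVC reference recovers the injected maximum", {
  cfg <- generator_config(seed = 31)
  prof <- participant_profile("PQ", 8)
  ref <- mvc_reference(generate_mvc(prof, cfg, 3))
  # stochastic-carrier envelope estimator: a priori ~8% sd, max over plateau
  expect_equal(unname(ref), unname(prof$mvc_max), tolerance = 0.3)
})

test_that("scaling raw EMG leaves normalized features unchanged", {
  cohort <- tiny_cohort()
  p <- cohort$participants[[2]]
  k <- 3.7
  tr <- p$trials[["db_0_15"]]
  scaled_trial <- emg_recording(tr$emg$signals * k, fs = tr$emg$fs)
  scaled_mvc <- emg_recording(p$mvc$signals * k, fs = p$mvc$fs, role = "mvc")
  env1 <- preprocess_emg(tr$emg)$envelope
  env2 <- preprocess_emg(scaled_trial)$envelope
  expect_equal(env2, k * env1, tolerance = 1e-9)
  steps <- segment_steps(tr$kinematics$heel_strikes)
  f1 <- trial_emg_features(tr$emg, mvc_reference(p$mvc), steps)
  f2 <- trial_emg_features(scaled_trial, mvc_reference(scaled_mvc), steps)
  expect_equal(f1$values, f2$values, tolerance = 1e-9)
})

test_that("step-based EMG features match a brute-force oracle", {
  set.seed(77)
  fs <- 200
  n <- 2000
  steps <- data.frame(
    start_s = c(1, 2, 3, 4), end_s = c(2, 3, 4, 5),
    side = c("R", "L", "R", "L")
  )
  env <- make_env(two_chan(stats::runif(n), stats::runif(n)), fs = fs)
  f <- trial_emg_step_features(env, steps)
  expect_equal(length(f), 8)
  t <- (seq_len(n) - 1) / fs
  for (m in c("ES_L", "ES_R")) {
    for (s in c("L", "R")) {
      rows <- which(steps$side == s)
      mvals <- rvals <- numeric(0)
      for (i in rows) {
        w <- env$envelope[t >= steps$start_s[i] & t < steps$end_s[i], m]
        mvals <- c(mvals, sum(w) / length(w))
        rvals <- c(rvals, sqrt(sum(w^2) / length(w)))
      }
      expect_equal(unname(f[paste0(m, "|mean|", s, "steps")]), mean(mvals), tolerance = 1e-12)
      expect_equal(unname(f[paste0(m, "|rms|", s, "steps")]), mean(rvals), tolerance = 1e-12)
    }
  }
  # constant envelope: mean = RMS = the constant on both sides
  cst <- make_env(two_chan(rep(0.4, n), rep(0.7, n)), fs = fs)
  fc <- trial_emg_step_features(cst, steps)
  expect_equal(unname(fc[c("ES_L|mean|Lsteps", "ES_L|rms|Rsteps")]), c(0.4, 0.4))
  expect_equal(unname(fc[c("ES_R|mean|Rsteps", "ES_R|rms|Lsteps")]), c(0.7, 0.7))
})

test_that("peak features implement the amplitude/duration gates", {
  fs <- 500
  t <- seq(0, 6, by = 1 / fs)
  # flat envelope below the 10% MVC gate -> no peaks
  flat <- make_env(two_chan(rep(0.05, length(t))), fs = fs)
  expect_equal(unname(trial_emg_peak_features(flat)), c(0, 0))
  # one smooth bump, FWHM ~0.4 s -> a single qualifying peak
  bump <- 0.5 * exp(-(t - 3)^2 / (2 * 0.17^2)) + 0.01
  one <- make_env(two_chan(bump), fs = fs)
  pk <- find_envelope_peaks(one$envelope[, 1], fs)
  expect_equal(nrow(pk), 1)
  expect_gt(pk$duration_s, 0.2)
  expect_equal(unname(trial_emg_peak_features(one)), c(0.51, 0.51), tolerance = 1e-3)
  # three qualifying bumps -> the median amplitude
  three <- 0.3 * exp(-(t - 1)^2 / (2 * 0.15^2)) +
    0.5 * exp(-(t - 3)^2 / (2 * 0.15^2)) +
    0.4 * exp(-(t - 5)^2 / (2 * 0.15^2)) + 0.001
  fm <- trial_emg_peak_features(make_env(two_chan(three), fs = fs))
  expect_equal(unname(fm), c(0.4, 0.4), tolerance = 5e-3)
  # a tall but too-brief spike is rejected by the duration gate
  brief <- 0.6 * exp(-(t - 3)^2 / (2 * 0.03^2)) + 0.01
  expect_equal(unname(trial_emg_peak_features(make_env(two_chan(brief), fs = fs))), c(0, 0))
})

test_that("peak detection matches the reference scan on random envelopes", {
  set.seed(505)
  fs <- 500
  for (i in 1:100) {
    x <- random_envelope(n = 2500, fs = fs)
    got <- find_envelope_peaks(x, fs)
    want <- oracle_peaks(x, fs)
    expect_equal(got$index, want$index)
    expect_equal(got$amplitude, want$amplitude, tolerance = 1e-9)
    expect_equal(got$duration_s, want$duration_s, tolerance = 1e-9)
  }
})

test_that("a missing EMG stream zero-fills the 10 features", {
  steps <- data.frame(start_s = 0, end_s = 1, side = "L")
  f <- trial_emg_features(NULL, NULL, steps)
  expect_true(f$missing_emg)
  expect_equal(length(f$values), 10)
  expect_true(all(f$values == 0))
  expect_equal(names(f$values), emg_feature_names())
})
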