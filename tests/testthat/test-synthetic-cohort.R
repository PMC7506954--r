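test_that("generator config validates its fields", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(box_arm_posture_deg = -1), "box_arm_posture_deg")
  expect_error(generator_config(emg_noise_level = NA), "emg_noise_level")
  expect_error(generator_config(emg_fs = 500), "emg_fs")
})

test_that("a cohort has the full trial grid and is seed-deterministic", {
  cohort <- tiny_cohort()
  expect_equal(length(cohort$participants), 2)
  for (p in cohort$participants) {
    expect_equal(length(p$trials), 19)
    expect_setequal(names(p$trials), load_conditions()$condition_id)
    expect_setequal(p$trial_order, load_conditions()$condition_id)
    expect_equal(p$mvc$role, "mvc")
  }
  # per-participant trial orders are shuffled independently
  expect_false(identical(
    cohort$participants[[1]]$trial_order,
    cohort$participants[[2]]$trial_order
  ))
  # identical config twice -> identical dataset
  again <- generate_cohort(2, generator_config(seed = 11))
  expect_identical(cohort$participants[[2]]$trials[["db_5_25"]]$kinematics$angles,
    again$participants[[2]]$trials[["db_5_25"]]$kinematics$angles)
  expect_identical(cohort$participants[[1]]$mvc$signals, again$participants[[1]]$mvc$signals)
  expect_error(generate_cohort(1, generator_config()), "at least 2")
})

test_that("trial waveforms are deterministic given profile, condition and seed", {
  cfg <- generator_config(
    seed = 5, kinematic_noise_deg = 0, emg_noise_level = 0,
    hs_jitter_s = 0
  )
  prof <- participant_profile("PX", 42)
  cond <- load_conditions()
  t1 <- generate_trial(prof, cond[cond$condition_id == "db_15_15", ], cfg, 7)
  t2 <- generate_trial(prof, cond[cond$condition_id == "db_15_15", ], cfg, 7)
  expect_identical(t1$kinematics$angles, t2$kinematics$angles)
  expect_identical(t1$emg$signals, t2$emg$signals)
  # with zero noise and jitter the heel strikes are perfectly periodic
  dt <- diff(t1$kinematics$heel_strikes$time_s)
  expect_equal(dt, rep(prof$stride_period_s / 2, length(dt)))
})

test_that("every generated trial carries 66 named, finite channels and events", {
  cohort <- tiny_cohort()
  tr <- cohort$participants[[1]]$trials[["box_25_5"]]
  expect_setequal(colnames(tr$kinematics$angles), kinematic_channels()$channel)
  expect_false(anyNA(tr$kinematics$angles))
  hs <- tr$kinematics$heel_strikes
  expect_equal(nrow(hs), cohort$participants[[1]]$profile$n_steps + 1)
  expect_true(all(diff(hs$time_s) > 0))
  expect_true(all(hs$side[-1] != hs$side[-nrow(hs)]))
})

test_that("box carries raise elbow flexion and abolish arm swing", {
  cohort <- tiny_cohort()
  cfg <- cohort$config
  for (p in cohort$participants) {
    box <- p$trials[["box_15_15"]]$kinematics$angles
    none <- p$trials[["none"]]$kinematics$angles
    for (ch in c("R elbow|flexion/extension", "L elbow|flexion/extension")) {
      expect_gt(mean(box[, ch]) - mean(none[, ch]), cfg$box_arm_posture_deg / 2)
    }
    sw <- "R shoulder|flexion/extension"
    expect_lt(stats::var(box[, sw]), stats::var(none[, sw]) / 4)
  }
})

test_that("a dumbbell suppresses same-side wrist variability (and its mirror)", {
  cohort <- tiny_cohort()
  for (p in cohort$participants) {
    left <- p$trials[["db_25_0"]]$kinematics$angles
    right <- p$trials[["db_0_25"]]$kinematics$angles
    lw <- "L wrist|pronation/supination"
    rw <- "R wrist|pronation/supination"
    expect_lt(stats::var(left[, lw]), stats::var(left[, rw]))
    expect_lt(stats::var(right[, rw]), stats::var(right[, lw]))
  }
})

test_that("loading effects are monotone in dumbbell weight at fixed seed", {
  cfg <- generator_config(seed = 3)
  prof <- participant_profile("PM", 21)
  cond <- load_conditions()
  wrist_var <- emg_mean <- numeric(0)
  for (cid in c("db_5_0", "db_25_0")) {
    tr <- generate_trial(prof, cond[cond$condition_id == cid, ], cfg, 77)
    wrist_var[cid] <- stats::var(tr$kinematics$angles[, "L wrist|pronation/supination"])
    env <- preprocess_emg(tr$emg)$envelope
    emg_mean[cid] <- mean(env[, "ES_R"])
  }
  # heavier left dumbbell: less left-wrist motion, more right-side EMG
  expect_lt(wrist_var["db_25_0"], wrist_var["db_5_0"])
  expect_gt(emg_mean["db_25_0"], emg_mean["db_5_0"])
})

test_that("asymmetric carries load the contralateral erector spinae", {
  cohort <- tiny_cohort()
  for (p in cohort$participants) {
    tr <- p$trials[["db_0_25"]]$emg # 25 lb in the right hand
    env <- preprocess_emg(tr)$envelope
    expect_gt(mean(env[, "ES_L"]), mean(env[, "ES_R"]))
  }
})

test_that("the MVC recording dominates trial envelopes and lasts ~5 s", {
  cohort <- tiny_cohort()
  p <- cohort$participants[[1]]
  mvc_env <- preprocess_emg(p$mvc)$envelope
  expect_equal(nrow(p$mvc$signals) / p$mvc$fs, 5, tolerance = 0.01)
  heavy_env <- preprocess_emg(p$trials[["db_25_25"]]$emg)$envelope
  for (m in c("ES_L", "ES_R")) {
    expect_gt(max(mvc_env[, m]), max(heavy_env[, m]))
  }
})

test_that("a noise-free MVC envelope plateaus near the configured maximum", {
  # the envelope estimator of a stochastic carrier keeps ~8% sampling
  # noise even without an additive noise floor; bound chosen a priori
  cfg <- generator_config(seed = 9, emg_noise_level = 0)
  prof <- participant_profile("PZ", 5)
  env <- preprocess_emg(generate_mvc(prof, cfg, 13))$envelope
  for (m in c("ES_L", "ES_R")) {
    expect_equal(max(env[, m]), unname(prof$mvc_max[m]), tolerance = 0.25)
  }
})
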