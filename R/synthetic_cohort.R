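# Seeded synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis relies on:
# periodic joint-angle trajectories over ~10-14 steps bracketed by quiet
# standing, heel-strike event streams, and burst-per-stance erector spinae
# EMG whose amplitude grows with carried load and predominantly with the
# load on the *opposite* side. Carrying effects on kinematics: a large
# elbow-flexion offset with suppressed arm swing for box carries, reduced
# arm-swing/wrist-angle amplitude on a loaded side for dumbbell carries,
# and a lateral trunk lean proportional to the signed left/right load
# difference (positive lean = toward the right).

#' Configuration of the synthetic cohort generator
#'
#' All effect sizes are non-negative; setting one to zero removes that
#' effect. Defaults are chosen to be physiologically plausible and to
#' reproduce the qualitative patterns the analysis assumes; they are the
#' package's reference study conditions, not tuning knobs.
#'
#' @param kinematic_fs Joint-angle sampling rate, Hz.
#' @param emg_fs EMG sampling rate, Hz.
#' @param box_arm_posture_deg Elbow-flexion offset (degrees) added on both
#'   arms when carrying the box in front of the body.
#' @param armswing_suppression_per_lb Fractional reduction of arm-swing
#'   (shoulder/elbow flexion-extension) amplitude per pound held on that
#'   side; amplitude factor is `max(0, 1 - rate * weight)`.
#' @param wrist_variability_suppression_per_lb Same, for the three wrist
#'   angle channels of the loaded side.
#' @param trunk_lean_deg_per_lb Lateral trunk-bending offset in degrees per
#'   pound of signed (right minus left) load difference.
#' @param emg_burst_base Baseline erector spinae burst amplitude during
#'   unloaded gait, as a fraction of the nominal MVC scale.
#' @param emg_load_gain_per_lb Burst-amplitude increase per pound carried
#'   on the muscle's own side.
#' @param emg_contralateral_gain_per_lb Burst-amplitude increase per pound
#'   carried on the opposite side (dominates the ipsilateral term).
#' @param kinematic_noise_deg Std. dev. of additive white measurement noise
#'   on every joint-angle channel, degrees.
#' @param emg_noise_level Std. dev. of the additive broadband EMG noise
#'   floor, on the normalized amplitude scale.
#' @param hs_jitter_s Std. dev. of heel-strike timing jitter, seconds.
#' @param standstill_pad_s Quiet standing before the first and after the
#'   last heel strike, seconds.
#' @param seed Root seed; all per-participant and per-trial seeds are
#'   derived from it deterministically.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(kinematic_fs = 240,
                             emg_fs = 2148,
                             box_arm_posture_deg = 70,
                             armswing_suppression_per_lb = 0.03,
                             wrist_variability_suppression_per_lb = 0.03,
                             trunk_lean_deg_per_lb = 0.12,
                             emg_burst_base = 0.20,
                             emg_load_gain_per_lb = 0.004,
                             emg_contralateral_gain_per_lb = 0.012,
                             kinematic_noise_deg = 1.0,
                             emg_noise_level = 0.02,
                             hs_jitter_s = 0.010,
                             standstill_pad_s = 1.5,
                             seed = 1L) {
  cfg <- list(
    kinematic_fs = kinematic_fs, emg_fs = emg_fs,
    box_arm_posture_deg = box_arm_posture_deg,
    armswing_suppression_per_lb = armswing_suppression_per_lb,
    wrist_variability_suppression_per_lb = wrist_variability_suppression_per_lb,
    trunk_lean_deg_per_lb = trunk_lean_deg_per_lb,
    emg_burst_base = emg_burst_base,
    emg_load_gain_per_lb = emg_load_gain_per_lb,
    emg_contralateral_gain_per_lb = emg_contralateral_gain_per_lb,
    kinematic_noise_deg = kinematic_noise_deg,
    emg_noise_level = emg_noise_level,
    hs_jitter_s = hs_jitter_s,
    standstill_pad_s = standstill_pad_s,
    seed = as.integer(seed)
  )
  for (f in setdiff(names(cfg), "seed")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop("invalid generator config: field `", f, "` must be a non-negative number")
    }
  }
  if (cfg$kinematic_fs <= 0) stop("invalid generator config: field `kinematic_fs` must be positive")
  if (cfg$emg_fs <= 900) stop("invalid generator config: field `emg_fs` must exceed 900 Hz")
  if (is.na(cfg$seed)) stop("invalid generator config: field `seed` must be an integer")
  structure(cfg, class = "generator_config")
}

# Deterministic child-seed derivation: one root seed fans out to
# per-participant (trial = 0) and per-trial streams. Kept below 2^31.
child_seed <- function(root, participant_index, trial_index = 0L) {
  ((as.numeric(root) %% 1e6) * 1009 +
    participant_index * 10007 + trial_index * 101) %% 2147483629 + 1
}

# Evaluate `code` under a temporary RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Draw a participant profile
#'
#' Participant-level random effects: nominal stride period, steps per
#' trial, per-joint amplitude gains, per-channel posture offsets, an EMG
#' gain and per-muscle MVC envelope maxima.
#'
#' @param participant_id String id.
#' @param seed Integer seed for this participant's draws.
#' @return A list of class `participant_profile`.
#' @export
participant_profile <- function(participant_id, seed) {
  ch <- kinematic_channels()
  joints <- unique(ch$joint)
  with_seed(seed, {
    prof <- list(
      participant_id = as.character(participant_id),
      stride_period_s = stats::runif(1, 1.00, 1.25),
      n_steps = sample(10:14, 1),
      joint_gain = stats::setNames(stats::runif(length(joints), 0.85, 1.15), joints),
      baseline_offset_deg = stats::setNames(stats::rnorm(nrow(ch), 0, 1.5), ch$channel),
      emg_gain = stats::runif(1, 0.85, 1.15),
      mvc_max = stats::setNames(stats::runif(2, 0.9, 1.1), c("ES_L", "ES_R"))
    )
    class(prof) <- "participant_profile"
    prof
  })
}

# Nominal per-channel waveform parameters: peak amplitude of the
# fundamental (degrees) and a resting posture offset (degrees), by joint
# group and plane. Loosely modeled on normative gait curves; the pipeline
# only consumes per-step moments, so exact shapes are free.
channel_base_params <- function() {
  ch <- kinematic_channels()
  amp_table <- list(
    spine = c("lateral bending" = 3, "axial bending" = 5, "flexion/extension" = 4),
    t4shoulder = c(
      "abduction/adduction" = 4, "internal/external rotation" = 4,
      "flexion/extension" = 6
    ),
    shoulder = c(
      "abduction/adduction" = 5, "internal/external rotation" = 5,
      "flexion/extension" = 20
    ),
    elbow = c(
      "ulnar/radial deviation" = 3, "pronation/supination" = 8,
      "flexion/extension" = 15
    ),
    wrist = c(
      "ulnar/radial deviation" = 5, "pronation/supination" = 10,
      "flexion/extension" = 8
    ),
    hip = c(
      "abduction/adduction" = 6, "internal/external rotation" = 6,
      "flexion/extension" = 35
    ),
    knee = c(
      "abduction/adduction" = 4, "internal/external rotation" = 5,
      "flexion/extension" = 60
    ),
    ankle = c(
      "abduction/adduction" = 4, "internal/external rotation" = 6,
      "flexion/extension" = 25
    ),
    ballfoot = c(
      "abduction/adduction" = 2, "internal/external rotation" = 3,
      "flexion/extension" = 10
    )
  )
  offset_table <- c(elbow = 10, knee = 15)
  ch$amp <- mapply(function(g, p) amp_table[[g]][[p]], ch$group, ch$plane)
  ch$offset0 <- ifelse(ch$group %in% names(offset_table) & ch$plane == "flexion/extension",
    offset_table[ch$group], 0
  )
  # fixed per-channel phase (quasi-irrational spacing); left side anti-phase
  # to the right so arms and legs swing in opposition
  ch$phase <- 2 * pi * ((seq_len(nrow(ch)) * 0.3619) %% 1) +
    ifelse(ch$side == "L", pi, 0)
  ch
}

# Amplitude multipliers and additive offsets a load condition applies to
# each channel.
condition_channel_effects <- function(condition, cfg) {
  ch <- channel_base_params()
  mult <- rep(1, nrow(ch))
  offs <- rep(0, nrow(ch))
  swing_ch <- ch$group %in% c("shoulder", "elbow") & ch$plane == "flexion/extension"
  arm_other <- ch$group %in% c("shoulder", "elbow", "t4shoulder") & !swing_ch
  if (condition$carry_mode == "box") {
    # both hands fixed on the box: arms raised, swing almost gone. The
    # whole frontal-carry postural effect scales with box_arm_posture_deg
    # (its default, 70 deg, gives the full effect; 0 removes it).
    strength <- min(1, cfg$box_arm_posture_deg / 70)
    elbow_flex <- ch$group == "elbow" & ch$plane == "flexion/extension"
    shoulder_flex <- ch$group == "shoulder" & ch$plane == "flexion/extension"
    offs[elbow_flex] <- offs[elbow_flex] + cfg$box_arm_posture_deg
    offs[shoulder_flex] <- offs[shoulder_flex] + cfg$box_arm_posture_deg / 3
    mult[swing_ch] <- 1 - 0.95 * strength
    mult[ch$group == "wrist"] <- 1 - 0.8 * strength
    mult[arm_other] <- 1 - 0.5 * strength
  } else if (condition$carry_mode == "dumbbells") {
    for (s in c("L", "R")) {
      w <- if (s == "L") condition$left_lb else condition$right_lb
      if (w > 0) {
        f_swing <- max(0, 1 - cfg$armswing_suppression_per_lb * w)
        f_wrist <- max(0, 1 - cfg$wrist_variability_suppression_per_lb * w)
        mult[swing_ch & ch$side == s] <- mult[swing_ch & ch$side == s] * f_swing
        mult[ch$group == "wrist" & ch$side == s] <-
          mult[ch$group == "wrist" & ch$side == s] * f_wrist
      }
    }
  }
  lean <- cfg$trunk_lean_deg_per_lb * (condition$right_lb - condition$left_lb)
  offs[ch$group == "spine" & ch$plane == "lateral bending"] <-
    offs[ch$group == "spine" & ch$plane == "lateral bending"] + lean
  list(channels = ch, mult = mult, offset = offs)
}

# Band-limited (20-450 Hz) unit-RMS Gaussian carrier for EMG synthesis.
emg_carrier <- function(n, fs) {
  bp <- signal::butter(2, c(20, 450) / (fs / 2), type = "pass")
  x <- signal::filter(bp, stats::rnorm(n))
  x <- as.numeric(x)
  x / stats::sd(x)
}

#' Generate one synthetic carrying trial
#'
#' Produces time-aligned kinematic and EMG recordings for one participant
#' and load condition. Kinematics are truncated-Fourier gait waveforms
#' (3 harmonics of the stride frequency, fixed per-channel phases) with
#' condition effects applied; heel strikes alternate sides every half
#' stride with timing jitter, bracketed by quiet standing. EMG is a
#' broadband noise carrier amplitude-modulated by one Gaussian burst per
#' stance phase per muscle; the carrier is scaled so that the rectified,
#' 10 Hz low-passed envelope is an unbiased estimate of the modulation.
#'
#' @param profile A [participant_profile()].
#' @param condition One row of [load_conditions()].
#' @param cfg A [generator_config()].
#' @param seed Integer seed for this trial's draws.
#' @return A [trial_record()].
#' @export
generate_trial <- function(profile, condition, cfg, seed) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.data.frame(condition)) {
    stopifnot(nrow(condition) == 1)
    condition <- as.list(condition)
  }
  with_seed(seed, {
    stride <- profile$stride_period_s
    step_dur <- stride / 2
    n_steps <- profile$n_steps
    pad <- cfg$standstill_pad_s

    # heel strikes: n_steps + 1 alternating events bounding n_steps steps
    hs_t <- pad + (0:n_steps) * step_dur + stats::rnorm(n_steps + 1, 0, cfg$hs_jitter_s)
    hs_t <- cummax_strict(hs_t, min_gap = 0.2 * step_dur)
    first_side <- sample(c("L", "R"), 1)
    sides <- rep(c(first_side, setdiff(c("L", "R"), first_side)),
      length.out = n_steps + 1
    )
    heel_strikes <- data.frame(time_s = hs_t, side = sides)

    t_end <- hs_t[length(hs_t)] + pad
    n_kin <- ceiling(t_end * cfg$kinematic_fs) + 1
    t_kin <- (seq_len(n_kin) - 1) / cfg$kinematic_fs

    eff <- condition_channel_effects(condition, cfg)
    ch <- eff$channels
    amp <- ch$amp * eff$mult * profile$joint_gain[ch$joint]
    offset <- ch$offset0 + eff$offset + profile$baseline_offset_deg[ch$channel]

    # gait on/off envelope: ramps over 0.4 s around first/last heel strike
    g <- ramp_window(t_kin, hs_t[1], hs_t[length(hs_t)], 0.4)
    theta <- 2 * pi * (t_kin - hs_t[1]) / stride
    harm_rel <- c(1, 0.35, 0.15)
    cosH <- cbind(cos(theta), cos(2 * theta), cos(3 * theta))
    sinH <- cbind(sin(theta), sin(2 * theta), sin(3 * theta))
    wave <- matrix(0, n_kin, nrow(ch))
    for (h in 1:3) {
      ph <- h * ch$phase
      wave <- wave + cosH[, h] %*% t(harm_rel[h] * amp * cos(ph)) -
        sinH[, h] %*% t(harm_rel[h] * amp * sin(ph))
    }
    angles <- g * wave +
      matrix(offset, n_kin, nrow(ch), byrow = TRUE) +
      matrix(stats::rnorm(n_kin * nrow(ch), 0, cfg$kinematic_noise_deg), n_kin)
    colnames(angles) <- ch$channel
    kin <- kinematic_recording(angles, heel_strikes, fs = cfg$kinematic_fs, t0 = 0)

    n_emg <- ceiling(t_end * cfg$emg_fs) + 1
    t_emg <- (seq_len(n_emg) - 1) / cfg$emg_fs
    sig <- matrix(0, n_emg, 2, dimnames = list(NULL, c("ES_L", "ES_R")))
    for (m in c("ES_L", "ES_R")) {
      own <- if (m == "ES_L") condition$left_lb else condition$right_lb
      contra <- if (m == "ES_L") condition$right_lb else condition$left_lb
      burst_amp <- profile$emg_gain * (cfg$emg_burst_base +
        cfg$emg_load_gain_per_lb * own +
        cfg$emg_contralateral_gain_per_lb * contra)
      side <- sub("ES_", "", m)
      centers <- heel_strikes$time_s[heel_strikes$side == side] + 0.15 * stride
      mod <- burst_train(t_emg, centers, burst_amp, sigma = 0.08 * stride) + 0.01
      sig[, m] <- mod * sqrt(pi / 2) * emg_carrier(n_emg, cfg$emg_fs) +
        cfg$emg_noise_level * emg_carrier(n_emg, cfg$emg_fs)
    }
    emg <- emg_recording(sig, fs = cfg$emg_fs, role = "trial")
    trial_record(profile$participant_id, condition$condition_id, kin, emg)
  })
}

# strictly increasing event times with a minimum gap (repairs rare jitter
# collisions without changing the typical stream)
cummax_strict <- function(x, min_gap) {
  for (i in seq_along(x)[-1]) {
    if (x[i] < x[i - 1] + min_gap) x[i] <- x[i - 1] + min_gap
  }
  x
}

# smooth 0->1->0 window with linear ramps of length `ramp` centered on the
# two boundaries
ramp_window <- function(t, t_on, t_off, ramp) {
  pmin(1, pmax(0, pmin((t - t_on + ramp / 2) / ramp, (t_off + ramp / 2 - t) / ramp)))
}

# sum of Gaussian bursts, evaluated only on +-4 sigma windows for speed
burst_train <- function(t, centers, amplitude, sigma) {
  out <- numeric(length(t))
  dt <- t[2] - t[1]
  for (c0 in centers) {
    i0 <- max(1, floor((c0 - 4 * sigma) / dt) + 1)
    i1 <- min(length(t), ceiling((c0 + 4 * sigma) / dt) + 1)
    idx <- i0:i1
    out[idx] <- out[idx] + amplitude * exp(-(t[idx] - c0)^2 / (2 * sigma^2))
  }
  out
}

#' Generate a maximum-voluntary-contraction (MVC) reference recording
#'
#' A ~5 s recording whose modulation is a sustained plateau at the
#' participant's `mvc_max` per muscle, so that the processed envelope
#' maximum of the MVC exceeds that of any carrying trial and trial
#' envelopes normalize into `[0, 1]` up to noise.
#'
#' @inheritParams generate_trial
#' @return An [emg_recording()] with role `"mvc"`.
#' @export
generate_mvc <- function(profile, cfg, seed) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(seed, {
    dur <- 5
    n <- ceiling(dur * cfg$emg_fs) + 1
    t <- (seq_len(n) - 1) / cfg$emg_fs
    plateau <- ramp_window(t, 0.75, dur - 0.75, 0.8)
    sig <- matrix(0, n, 2, dimnames = list(NULL, c("ES_L", "ES_R")))
    for (m in c("ES_L", "ES_R")) {
      mod <- profile$mvc_max[[m]] * plateau + 0.01
      sig[, m] <- mod * sqrt(pi / 2) * emg_carrier(n, cfg$emg_fs) +
        cfg$emg_noise_level * emg_carrier(n, cfg$emg_fs)
    }
    emg_recording(sig, fs = cfg$emg_fs, role = "mvc")
  })
}

#' Generate a full synthetic cohort
#'
#' Each participant completes all 19 load conditions, one trial each, in a
#' per-participant seeded shuffled order, plus one MVC reference recording.
#' Identical `(n_participants, cfg)` (including `cfg$seed`) yield identical
#' output.
#'
#' @param n_participants Number of participants (>= 2).
#' @param cfg A [generator_config()].
#' @return An object of class `gait_cohort`: a list with `config` and
#'   `participants`, each participant holding `profile`, `trial_order`,
#'   `trials` (named list of [trial_record()]) and `mvc`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(2, generator_config(seed = 7))
#' length(cohort$participants[[1]]$trials) # 19
#' }
#' @export
generate_cohort <- function(n_participants, cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.numeric(n_participants) || n_participants < 2) {
    stop("n_participants must be at least 2")
  }
  conditions <- load_conditions()
  participants <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    pid <- sprintf("P%02d", i)
    prof <- participant_profile(pid, child_seed(cfg$seed, i, 0L))
    order_i <- with_seed(child_seed(cfg$seed, i, 998L), sample.int(19))
    trials <- vector("list", 19)
    for (k in seq_len(19)) {
      j <- order_i[k]
      trials[[j]] <- generate_trial(
        prof, conditions[j, ], cfg,
        seed = child_seed(cfg$seed, i, j)
      )
    }
    names(trials) <- conditions$condition_id
    mvc <- generate_mvc(prof, cfg, seed = child_seed(cfg$seed, i, 999L))
    participants[[i]] <- list(
      profile = prof,
      trial_order = conditions$condition_id[order_i],
      trials = trials, mvc = mvc
    )
  }
  names(participants) <- vapply(participants, function(p) p$profile$participant_id, "")
  structure(list(config = cfg, participants = participants), class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(
    "<gait_cohort>", length(x$participants), "participants x",
    length(x$participants[[1]]$trials), "trials, seed", x$config$seed, "\n"
  )
  invisible(x)
}
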