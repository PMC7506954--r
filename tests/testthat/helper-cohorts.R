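# Memoized synthetic cohorts so multiple test files can share the
# (comparatively expensive) generation + feature-extraction work.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

cached_cohort <- function(n_participants, cfg) {
  key <- paste(c("cohort", n_participants, unlist(cfg)), collapse = "|")
  memo(key, generate_cohort(n_participants, cfg))
}

cached_features <- function(n_participants, cfg) {
  key <- paste(c("features", n_participants, unlist(cfg)), collapse = "|")
  memo(key, cohort_features(cached_cohort(n_participants, cfg)))
}

# small default-config cohort for unit tests
tiny_cohort <- function() cached_cohort(2, generator_config(seed = 11))
tiny_features <- function() cached_features(2, generator_config(seed = 11))

# study conditions for the acceptance experiments
default_config <- function(seed) generator_config(seed = seed)

# EMG-lift condition: kinematic asymmetry effects weak, contralateral EMG
# effect strong
emg_lift_config <- function(seed) {
  generator_config(
    seed = seed,
    trunk_lean_deg_per_lb = 0.02,
    armswing_suppression_per_lb = 0.005,
    wrist_variability_suppression_per_lb = 0.005,
    emg_contralateral_gain_per_lb = 0.02
  )
}

# null condition: every load effect removed
null_config <- function(seed) {
  generator_config(
    seed = seed,
    box_arm_posture_deg = 0,
    armswing_suppression_per_lb = 0,
    wrist_variability_suppression_per_lb = 0,
    trunk_lean_deg_per_lb = 0,
    emg_load_gain_per_lb = 0,
    emg_contralateral_gain_per_lb = 0
  )
}

# class-prior maximum (fraction) of a problem under the 19-condition protocol
class_prior_max <- function(problem) {
  counts <- class_counts(problem)
  max(counts) / sum(counts)
}
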