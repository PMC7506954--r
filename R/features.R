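#' Full 538-dimensional feature vector of one trial
#'
#' Segments the trial's heel strikes into steps (shared by both sensor
#' streams via the common trial clock), computes the 528 inertial and 10
#' EMG features, and returns them with missing-sensor flags. A missing
#' sensor stream contributes zeros and sets its flag.
#'
#' @param record A [trial_record()].
#' @param mvc_ref The participant's per-muscle MVC reference
#'   ([mvc_reference()]); required unless the trial's EMG is missing.
#' @return List with `values` (named numeric vector, length 538),
#'   `missing_inertial`, `missing_emg`.
#' @export
extract_trial_features <- function(record, mvc_ref = NULL) {
  stopifnot(inherits(record, "trial_record"))
  if (is.null(record$kinematics)) {
    stop("trial has no kinematic recording and therefore no heel strikes; ",
      "supply steps by attaching a kinematic recording",
      call. = FALSE
    )
  }
  steps <- segment_steps(record$kinematics$heel_strikes)
  inertial <- trial_inertial_features(record$kinematics, steps)
  if (!is.null(record$emg) && is.null(mvc_ref)) {
    stop("mvc_ref is required to normalize the trial's EMG envelope")
  }
  emg <- trial_emg_features(record$emg, mvc_ref, steps)
  list(
    values = c(inertial$values, emg$values),
    missing_inertial = inertial$missing_inertial,
    missing_emg = emg$missing_emg
  )
}

#' Feature matrix of a whole cohort
#'
#' One row per trial: metadata columns (`participant_id`, `condition_id`,
#' `missing_inertial`, `missing_emg`) followed by the 538 feature columns
#' in canonical order. Each participant's MVC reference is computed once
#' from their MVC recording.
#'
#' @param cohort A `gait_cohort` from [generate_cohort()].
#' @return A data.frame of class `trial_features` (non-syntactic feature
#'   names are preserved).
#' @export
cohort_features <- function(cohort) {
  stopifnot(inherits(cohort, "gait_cohort"))
  rows <- list()
  for (p in cohort$participants) {
    ref <- mvc_reference(p$mvc)
    for (trial in p$trials) {
      f <- extract_trial_features(trial, ref)
      rows[[length(rows) + 1]] <- c(
        list(
          participant_id = trial$participant_id,
          condition_id = trial$condition_id,
          missing_inertial = f$missing_inertial,
          missing_emg = f$missing_emg
        ),
        as.list(f$values)
      )
    }
  }
  out <- data.frame(
    participant_id = vapply(rows, `[[`, "", "participant_id"),
    condition_id = vapply(rows, `[[`, "", "condition_id"),
    missing_inertial = vapply(rows, `[[`, NA, "missing_inertial"),
    missing_emg = vapply(rows, `[[`, NA, "missing_emg"),
    check.names = FALSE
  )
  X <- do.call(rbind, lapply(rows, function(r) unlist(r[-(1:4)])))
  colnames(X) <- all_feature_names()
  out <- cbind(out, as.data.frame(X, check.names = FALSE))
  class(out) <- c("trial_features", "data.frame")
  out
}

feature_meta_columns <- function() {
  c("participant_id", "condition_id", "missing_inertial", "missing_emg")
}

#' Extract the numeric feature block of a feature matrix
#'
#' @param features A `trial_features` data.frame.
#' @param feature_set `"inertial"` (528 columns), `"emg"` (10) or
#'   `"both"` (538).
#' @return Numeric matrix with canonical column names.
#' @export
feature_block <- function(features, feature_set = c("both", "inertial", "emg")) {
  feature_set <- match.arg(feature_set)
  cols <- switch(feature_set,
    inertial = inertial_feature_names(),
    emg = emg_feature_names(),
    both = all_feature_names()
  )
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols) > 0) {
    stop("feature matrix lacks expected columns, e.g. ", missing_cols[1])
  }
  as.matrix(features[, cols, drop = FALSE])
}
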