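#' Construct a kinematic recording
#'
#' A kinematic recording holds the 66 joint-angle channels of one trial,
#' sampled on a common clock (seconds from trial start, `t0 = 0`), plus the
#' heel-strike event stream used for step segmentation. Heel-strike events
#' live on the same clock; the EMG stream of the same trial is aligned by
#' time, never by sample index, so the two streams may use different
#' sampling rates.
#'
#' @param angles Numeric matrix, one column per channel (degrees), column
#'   names exactly the 66 names of [kinematic_channels()].
#' @param heel_strikes data.frame with `time_s` (strictly increasing) and
#'   `side` (`"L"`/`"R"`).
#' @param fs Sampling rate in Hz (240 by default).
#' @param t0 Start time in seconds (0 by default).
#' @return An object of class `kinematic_recording`.
#' @export
kinematic_recording <- function(angles, heel_strikes, fs = 240, t0 = 0) {
  expected <- kinematic_channels()$channel
  if (is.null(colnames(angles)) || ncol(angles) != 66) {
    stop("kinematic recording must have exactly 66 named channels, got ", ncol(angles))
  }
  if (!setequal(colnames(angles), expected)) {
    missing <- setdiff(expected, colnames(angles))
    extra <- setdiff(colnames(angles), expected)
    stop(
      "kinematic channel names do not match the 66-channel convention",
      if (length(missing)) paste0("; missing: ", paste(utils::head(missing, 3), collapse = ", ")),
      if (length(extra)) paste0("; unexpected: ", paste(utils::head(extra, 3), collapse = ", "))
    )
  }
  if (anyNA(angles)) stop("kinematic channels contain NA values")
  validate_heel_strikes(heel_strikes)
  t_end <- t0 + (nrow(angles) - 1) / fs
  if (nrow(heel_strikes) > 0 &&
    (min(heel_strikes$time_s) < t0 || max(heel_strikes$time_s) > t_end)) {
    stop("heel-strike events fall outside the recording's time span")
  }
  structure(
    list(fs = fs, t0 = t0, angles = angles, heel_strikes = heel_strikes),
    class = "kinematic_recording"
  )
}

validate_heel_strikes <- function(heel_strikes) {
  if (!is.data.frame(heel_strikes) ||
    !all(c("time_s", "side") %in% names(heel_strikes))) {
    stop("heel_strikes must be a data.frame with columns time_s and side")
  }
  if (!all(heel_strikes$side %in% c("L", "R"))) {
    stop("heel-strike sides must be \"L\" or \"R\"")
  }
  if (nrow(heel_strikes) > 1 && any(diff(heel_strikes$time_s) <= 0)) {
    stop("heel-strike times must be strictly increasing")
  }
  invisible(TRUE)
}

#' Construct an EMG recording
#'
#' Two raw surface-EMG channels (left and right erector spinae) in
#' arbitrary amplitude units. The sampling rate must exceed 900 Hz so that
#' the 20-450 Hz bandpass of the preprocessing chain is representable.
#'
#' @param signals Numeric matrix with two columns named `ES_L` and `ES_R`.
#' @param fs Sampling rate in Hz (2148 by default).
#' @param role `"trial"` for a carrying trial, `"mvc"` for the
#'   maximum-voluntary-contraction reference recording.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signals, fs = 2148, role = c("trial", "mvc")) {
  role <- match.arg(role)
  if (is.null(colnames(signals)) || ncol(signals) != 2 ||
    !setequal(colnames(signals), c("ES_L", "ES_R"))) {
    stop("EMG recording must have exactly 2 channels named ES_L and ES_R")
  }
  if (fs <= 900) stop("EMG sampling rate must exceed 900 Hz, got ", fs)
  if (anyNA(signals)) stop("EMG channels contain NA values")
  structure(
    list(fs = fs, signals = signals[, c("ES_L", "ES_R"), drop = FALSE], role = role),
    class = "emg_recording"
  )
}

#' Construct a trial record
#'
#' Bundles one trial's kinematic and EMG recordings with its metadata.
#' Either sensor stream (but not both) may be missing, mirroring occasional
#' sensor-system data loss; downstream feature extraction zero-fills the
#' affected features and flags them.
#'
#' @param participant_id,condition_id Strings.
#' @param kinematics A [kinematic_recording()] or `NULL` if lost.
#' @param emg An [emg_recording()] with role `"trial"`, or `NULL` if lost.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(participant_id, condition_id, kinematics, emg) {
  if (is.null(kinematics) && is.null(emg)) {
    stop("at most one of the two sensor streams may be missing")
  }
  if (!is.null(kinematics) && !inherits(kinematics, "kinematic_recording")) {
    stop("`kinematics` must be a kinematic_recording or NULL")
  }
  if (!is.null(emg)) {
    if (!inherits(emg, "emg_recording")) stop("`emg` must be an emg_recording or NULL")
    if (emg$role != "trial") stop("a trial record's EMG must have role \"trial\"")
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      condition_id = as.character(condition_id),
      kinematics = kinematics, emg = emg
    ),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(
    "<trial_record>", x$participant_id, "/", x$condition_id,
    "| kinematics:", if (is.null(x$kinematics)) "MISSING" else
      paste0(nrow(x$kinematics$angles), " samples @ ", x$kinematics$fs, " Hz"),
    "| emg:", if (is.null(x$emg)) "MISSING" else
      paste0(nrow(x$emg$signals), " samples @ ", x$emg$fs, " Hz"), "\n"
  )
  invisible(x)
}
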