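# Plain-text interchange formats. One directory per trial:
#   meta.json       participant/condition ids, sampling metadata,
#                   heel-strike events, missing-sensor markers
#   kinematics.csv  time_s + 66 joint-angle channels (absent if missing)
#   emg.csv         time_s + ES_L + ES_R (absent if missing)
# Feature matrices are single CSV files with a header row. All numeric
# text is written with 15 significant digits, so round-trips are exact to
# well below 1e-9 relative error.

#' Write / read one trial to a directory of plain-text files
#'
#' `write_trial()` serializes a [trial_record()] to `meta.json` plus one
#' CSV per present sensor stream; `read_trial()` reconstructs it,
#' validating channel counts (66 kinematic, 2 EMG) and heel-strike
#' ordering. Missing sensor streams round-trip as missing.
#'
#' @param record A [trial_record()].
#' @param path Directory to write to (created if needed) / read from.
#' @return `write_trial()`: `path`, invisibly. `read_trial()`: a
#'   [trial_record()].
#' @export
write_trial <- function(record, path) {
  stopifnot(inherits(record, "trial_record"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format_version = "1.0",
    participant_id = record$participant_id,
    condition_id = record$condition_id,
    kinematics = if (is.null(record$kinematics)) {
      list(missing = TRUE)
    } else {
      list(
        missing = FALSE, fs = record$kinematics$fs, t0 = record$kinematics$t0,
        heel_strikes = record$kinematics$heel_strikes
      )
    },
    emg = if (is.null(record$emg)) {
      list(missing = TRUE)
    } else {
      list(missing = FALSE, fs = record$emg$fs, role = record$emg$role)
    }
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(record$kinematics)) {
    k <- record$kinematics
    t <- k$t0 + (seq_len(nrow(k$angles)) - 1) / k$fs
    dt <- data.table::as.data.table(cbind(time_s = t, k$angles))
    data.table::fwrite(dt, file.path(path, "kinematics.csv"))
  }
  if (!is.null(record$emg)) {
    t <- (seq_len(nrow(record$emg$signals)) - 1) / record$emg$fs
    dt <- data.table::as.data.table(cbind(time_s = t, record$emg$signals))
    data.table::fwrite(dt, file.path(path, "emg.csv"))
  }
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("no meta.json in ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("format_version", "participant_id", "condition_id", "kinematics", "emg")) {
    if (is.null(meta[[f]])) stop("malformed meta.json: missing field `", f, "`")
  }
  kin <- NULL
  if (!isTRUE(meta$kinematics$missing)) {
    dt <- data.table::fread(file.path(path, "kinematics.csv"), sep = ",", check.names = FALSE)
    if (!"time_s" %in% names(dt)) stop("malformed kinematics.csv: no time_s column")
    ang <- as.matrix(dt[, -1])
    if (ncol(ang) != 66) {
      stop("kinematics.csv has ", ncol(ang), " channels; expected 66")
    }
    hs <- as.data.frame(meta$kinematics$heel_strikes)
    kin <- kinematic_recording(ang, hs,
      fs = meta$kinematics$fs,
      t0 = meta$kinematics$t0
    )
  }
  emg <- NULL
  if (!isTRUE(meta$emg$missing)) {
    dt <- data.table::fread(file.path(path, "emg.csv"), sep = ",", check.names = FALSE)
    if (!"time_s" %in% names(dt)) stop("malformed emg.csv: no time_s column")
    sig <- as.matrix(dt[, -1])
    if (ncol(sig) != 2) stop("emg.csv has ", ncol(sig), " channels; expected 2")
    emg <- emg_recording(sig, fs = meta$emg$fs, role = meta$emg$role)
  }
  trial_record(meta$participant_id, meta$condition_id, kin, emg)
}

#' Write / read a trial feature matrix as CSV
#'
#' One row per trial; metadata columns first, then the canonical feature
#' columns. Column names (which contain `|` and spaces) are preserved
#' verbatim in the header.
#'
#' @param features A `trial_features` data.frame ([cohort_features()]).
#' @param path CSV file path.
#' @param check_schema For `read_feature_matrix()`: verify that the header
#'   carries the metadata columns plus the 538 canonical feature names
#'   (default `TRUE`).
#' @return `write_feature_matrix()`: `path`, invisibly;
#'   `read_feature_matrix()`: the `trial_features` data.frame.
#' @export
write_feature_matrix <- function(features, path) {
  if (anyDuplicated(names(features))) {
    stop(
      "duplicate feature names: ",
      paste(unique(names(features)[duplicated(names(features))]), collapse = ", ")
    )
  }
  data.table::fwrite(data.table::as.data.table(features), path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, check_schema = TRUE) {
  dt <- data.table::fread(path, sep = ",", header = TRUE, check.names = FALSE)
  out <- as.data.frame(dt, check.names = FALSE)
  if (anyDuplicated(names(out))) {
    stop("duplicate feature names in ", path)
  }
  if (check_schema) {
    expected <- c(feature_meta_columns(), all_feature_names())
    if (!identical(names(out), expected)) {
      missing_cols <- setdiff(expected, names(out))
      extra <- setdiff(names(out), expected)
      stop(
        "feature matrix header does not match the expected schema",
        if (length(missing_cols)) paste0("; missing: ", paste(utils::head(missing_cols, 3), collapse = ", ")),
        if (length(extra)) paste0("; unexpected: ", paste(utils::head(extra, 3), collapse = ", "))
      )
    }
  }
  if (nrow(out) > 0) {
    for (cc in c("missing_inertial", "missing_emg")) {
      if (cc %in% names(out)) out[[cc]] <- as.logical(out[[cc]])
    }
  }
  class(out) <- c("trial_features", "data.frame")
  out
}
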