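#' The 66 joint-angle channels
#'
#' The kinematic stream carries angles for 22 joints in 3 anatomical planes
#' each (66 channels). The joint list follows the 23-segment/22-joint
#' full-body biomechanical model of commercial IMU motion-capture suits:
#' six spine/neck joints and eight bilateral joint pairs. Plane names use
#' the clinical vocabulary of that model (flexion/extension,
#' abduction/adduction, internal/external rotation; pronation/supination
#' and ulnar/radial deviation at the elbow and wrist; lateral and axial
#' bending for the spine).
#'
#' Channel names follow the grammar `<joint>|<plane>`, e.g.
#' `"R elbow|flexion/extension"` or `"L4-L3|axial bending"`. This naming is
#' a convention of this package (the source motion-capture manual does not
#' prescribe a flat channel grammar).
#'
#' @return A data.frame with 66 rows: `joint`, `plane`, `side` (`"L"`,
#'   `"R"` or `"C"` for the midline), `group` (joint family, e.g.
#'   `"wrist"`, `"spine"`), and `channel` (the full channel name).
#' @export
kinematic_channels <- function() {
  spine_joints <- c("L5-S1", "L4-L3", "L1-T12", "T9-T8", "T1-C7", "C1-head")
  spine_planes <- c("lateral bending", "axial bending", "flexion/extension")
  limb_planes <- c("abduction/adduction", "internal/external rotation", "flexion/extension")
  arm_distal_planes <- c("ulnar/radial deviation", "pronation/supination", "flexion/extension")

  rows <- list()
  for (j in spine_joints) {
    rows[[length(rows) + 1]] <- data.frame(
      joint = j, plane = spine_planes, side = "C", group = "spine"
    )
  }
  bilateral <- list(
    c("T4-shoulder", "t4shoulder"), c("shoulder", "shoulder"),
    c("elbow", "elbow"), c("wrist", "wrist"),
    c("hip", "hip"), c("knee", "knee"),
    c("ankle", "ankle"), c("ball foot", "ballfoot")
  )
  for (b in bilateral) {
    planes <- if (b[2] %in% c("elbow", "wrist")) arm_distal_planes else limb_planes
    for (s in c("R", "L")) {
      rows[[length(rows) + 1]] <- data.frame(
        joint = paste(s, b[1]), plane = planes, side = s, group = b[2]
      )
    }
  }
  out <- do.call(rbind, rows)
  out$channel <- paste(out$joint, out$plane, sep = "|")
  stopifnot(nrow(out) == 66, !anyDuplicated(out$channel))
  rownames(out) <- NULL
  out
}

#' Canonical feature names
#'
#' Inertial feature names follow
#' `<joint>|<plane>|<raw|abs>|<mean|var>|<Lsteps|Rsteps>`: per step, the
#' mean and variance of the raw and of the absolute joint-angle signal are
#' computed, then averaged over all left steps and over all right steps
#' separately (66 channels x 4 moments x 2 step sides = 528 names).
#'
#' EMG feature names are `ES_<L|R>|<mean|rms>|<Lsteps|Rsteps>` for the 8
#' step-based envelope features and `ES_<L|R>|peakmedian` for the two
#' whole-trial peak-median features (10 names).
#'
#' @return Character vector of feature names in canonical column order.
#' @export
inertial_feature_names <- function() {
  ch <- kinematic_channels()$channel
  grid <- expand.grid(
    side = c("Lsteps", "Rsteps"),
    moment = c("mean", "var"),
    transform = c("raw", "abs"),
    channel = ch,
    stringsAsFactors = FALSE
  )
  # order: channel-major, then raw/abs, then mean/var, then L/R steps
  grid <- grid[order(
    match(grid$channel, ch), match(grid$transform, c("raw", "abs")),
    match(grid$moment, c("mean", "var")), match(grid$side, c("Lsteps", "Rsteps"))
  ), ]
  paste(grid$channel, grid$transform, grid$moment, grid$side, sep = "|")
}

#' @rdname inertial_feature_names
#' @export
emg_feature_names <- function() {
  step_based <- as.vector(outer(
    c("ES_L", "ES_R"),
    as.vector(outer(c("mean", "rms"), c("Lsteps", "Rsteps"), paste, sep = "|")),
    paste,
    sep = "|"
  ))
  c(sort(step_based), "ES_L|peakmedian", "ES_R|peakmedian")
}

#' @rdname inertial_feature_names
#' @export
all_feature_names <- function() {
  c(inertial_feature_names(), emg_feature_names())
}
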