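#' Per-step moments of a scalar signal window
#'
#' The four moments computed for every joint-angle channel within one
#' step: mean and variance of the raw signal, and mean and variance of its
#' absolute value. Variances use the sample (`n - 1`) denominator; a
#' single-sample window returns variance 0 with a warning.
#'
#' @param window Non-empty numeric vector (the samples of one step).
#' @return Named numeric vector `c(mean, var, mean_abs, var_abs)`.
#' @examples
#' step_moments(c(-1, 1)) # mean 0, var 2, mean_abs 1, var_abs 0
#' @export
step_moments <- function(window) {
  if (length(window) == 0) stop("empty window: step moments need at least one sample")
  if (length(window) == 1) {
    warning("single-sample step window: variance set to 0")
    return(c(mean = window, var = 0, mean_abs = abs(window), var_abs = 0))
  }
  c(
    mean = mean(window), var = stats::var(window),
    mean_abs = mean(abs(window)), var_abs = stats::var(abs(window))
  )
}

# per-step moment matrix for all channels at once: rows = steps, one
# block of columns per channel. Returns list(mean, var, mean_abs, var_abs)
# each a (#steps x #channels) matrix.
step_moment_matrices <- function(angles, t, steps) {
  ns <- nrow(steps)
  nc <- ncol(angles)
  out <- list(
    mean = matrix(NA_real_, ns, nc), var = matrix(NA_real_, ns, nc),
    mean_abs = matrix(NA_real_, ns, nc), var_abs = matrix(NA_real_, ns, nc)
  )
  for (k in seq_len(ns)) {
    idx <- t >= steps$start_s[k] & t < steps$end_s[k]
    w <- angles[idx, , drop = FALSE]
    if (nrow(w) == 0) stop("step window contains no kinematic samples")
    aw <- abs(w)
    out$mean[k, ] <- colMeans(w)
    out$mean_abs[k, ] <- colMeans(aw)
    if (nrow(w) == 1) {
      out$var[k, ] <- 0
      out$var_abs[k, ] <- 0
    } else {
      out$var[k, ] <- colSums((w - rep(out$mean[k, ], each = nrow(w)))^2) / (nrow(w) - 1)
      out$var_abs[k, ] <- colSums((aw - rep(out$mean_abs[k, ], each = nrow(w)))^2) / (nrow(w) - 1)
    }
  }
  out
}

#' The 528 inertial features of one trial
#'
#' For each of the 66 joint-angle channels, the four per-step moments
#' ([step_moments()]) are computed in every step window, then averaged over
#' all left steps and over all right steps separately: 66 channels x 4
#' moments x 2 step sides = 528 named features. A missing kinematic
#' recording yields all-zero features with `missing_inertial = TRUE`; a
#' trial with no valid steps on one side zero-fills that side's features
#' with a warning.
#'
#' @param kinematics A [kinematic_recording()] or `NULL` (missing sensor).
#' @param steps Step windows from [segment_steps()]; defaults to segmenting
#'   the recording's own heel strikes.
#' @return A list with `values` (named numeric vector of length 528, names
#'   from [inertial_feature_names()]) and `missing_inertial` (logical).
#' @export
trial_inertial_features <- function(kinematics, steps = NULL) {
  nm <- inertial_feature_names()
  if (is.null(kinematics)) {
    return(list(
      values = stats::setNames(rep(0, length(nm)), nm),
      missing_inertial = TRUE
    ))
  }
  stopifnot(inherits(kinematics, "kinematic_recording"))
  if (is.null(steps)) steps <- segment_steps(kinematics$heel_strikes)
  ch <- kinematic_channels()$channel
  angles <- kinematics$angles[, ch, drop = FALSE]
  t <- kinematics$t0 + (seq_len(nrow(angles)) - 1) / kinematics$fs
  mm <- step_moment_matrices(angles, t, steps)
  values <- stats::setNames(rep(0, length(nm)), nm)
  for (s in c("L", "R")) {
    rows <- which(steps$side == s)
    tag <- paste0(s, "steps")
    if (length(rows) == 0) {
      warning("no valid ", s, " steps: that side's inertial features set to 0")
      next
    }
    for (mom in c("mean", "var", "mean_abs", "var_abs")) {
      trans <- if (grepl("abs", mom)) "abs" else "raw"
      stat <- if (grepl("mean", mom)) "mean" else "var"
      key <- paste(ch, trans, stat, tag, sep = "|")
      values[key] <- colMeans(mm[[mom]][rows, , drop = FALSE])
    }
  }
  list(values = values, missing_inertial = FALSE)
}
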