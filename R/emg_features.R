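# EMG processing chain: linear detrend -> 2nd-order Butterworth 20-450 Hz
# bandpass -> full-wave rectification -> 2nd-order Butterworth 10 Hz
# lowpass envelope -> MVC normalization. All filters are applied
# forward-backward (zero phase), the standard offline practice.

linear_detrend <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), x)
  fit$residuals
}

apply_filtfilt <- function(filt, x) {
  as.numeric(signal::filtfilt(filt, x))
}

#' Preprocess a raw EMG recording
#'
#' Per channel: remove a linear trend, bandpass 20-450 Hz (2nd-order
#' Butterworth, zero phase), rectify, and extract the envelope with a
#' 10 Hz 2nd-order Butterworth lowpass (zero phase). Output lengths equal
#' the input length. The envelope is clamped at zero (the lowpass can
#' slightly undershoot near sharp onsets).
#'
#' @param raw An [emg_recording()].
#' @return List with `fs`, `rectified` (rectified bandpassed signals) and
#'   `envelope` (unnormalized envelope), both n x 2 matrices, of class
#'   `emg_envelope`.
#' @export
preprocess_emg <- function(raw) {
  stopifnot(inherits(raw, "emg_recording"))
  fs <- raw$fs
  n <- nrow(raw$signals)
  min_len <- 3 * ceiling(fs / 10) # 3x the 10 Hz filter's settling span
  if (n < min_len) {
    stop("EMG channel too short for stable filtering: ", n, " < ", min_len, " samples")
  }
  bp <- signal::butter(2, c(20, 450) / (fs / 2), type = "pass")
  lp <- signal::butter(2, 10 / (fs / 2), type = "low")
  rectified <- matrix(NA_real_, n, 2, dimnames = dimnames(raw$signals))
  envelope <- rectified
  for (j in 1:2) {
    filtered <- apply_filtfilt(bp, linear_detrend(raw$signals[, j]))
    rectified[, j] <- abs(filtered)
    envelope[, j] <- pmax(0, apply_filtfilt(lp, rectified[, j]))
  }
  structure(list(fs = fs, rectified = rectified, envelope = envelope),
    class = "emg_envelope"
  )
}

#' Per-muscle MVC normalization reference
#'
#' The maximum of the preprocessed (unnormalized) envelope of the
#' participant's maximum-voluntary-contraction recording, per channel.
#' Trial envelopes are divided by this reference so that features are
#' expressed as fractions of MVC.
#'
#' @param mvc An [emg_recording()] with role `"mvc"`.
#' @return Named numeric vector of length 2 (`ES_L`, `ES_R`).
#' @export
mvc_reference <- function(mvc) {
  stopifnot(inherits(mvc, "emg_recording"))
  if (mvc$role != "mvc") stop("mvc_reference() needs a recording with role \"mvc\"")
  env <- preprocess_emg(mvc)$envelope
  ref <- apply(env, 2, max)
  if (any(ref <= 0)) {
    stop("dead MVC channel: non-positive envelope maximum in ", paste(colnames(env)[ref <= 0], collapse = ", "))
  }
  ref
}

#' Normalize a trial envelope by the participant's MVC reference
#'
#' @param env An `emg_envelope` from [preprocess_emg()].
#' @param ref Per-muscle reference from [mvc_reference()].
#' @return The envelope object with `envelope` rescaled to fractions of
#'   MVC and a `normalized = TRUE` marker.
#' @export
normalize_envelope <- function(env, ref) {
  stopifnot(inherits(env, "emg_envelope"))
  env$envelope <- sweep(env$envelope, 2, ref[colnames(env$envelope)], "/")
  env$normalized <- TRUE
  env
}

#' The 8 step-based EMG features of a trial
#'
#' Per muscle, the mean and RMS of the normalized envelope are computed in
#' every step window, then averaged over all left and over all right
#' steps separately: 2 muscles x 2 statistics x 2 step sides = 8 named
#' features. A side without valid steps is zero-filled with a warning.
#'
#' @param env A normalized `emg_envelope` (see [normalize_envelope()]).
#' @param steps Step windows from [segment_steps()], on the shared trial
#'   clock (seconds from trial start).
#' @return Named numeric vector of length 8.
#' @export
trial_emg_step_features <- function(env, steps) {
  stopifnot(inherits(env, "emg_envelope"))
  t <- (seq_len(nrow(env$envelope)) - 1) / env$fs
  out <- numeric(0)
  for (m in c("ES_L", "ES_R")) {
    x <- env$envelope[, m]
    for (stat in c("mean", "rms")) {
      for (s in c("L", "R")) {
        rows <- which(steps$side == s)
        key <- paste(m, stat, paste0(s, "steps"), sep = "|")
        if (length(rows) == 0) {
          warning("no valid ", s, " steps: EMG feature ", key, " set to 0")
          out[key] <- 0
          next
        }
        per_step <- vapply(rows, function(k) {
          w <- x[t >= steps$start_s[k] & t < steps$end_s[k]]
          if (length(w) == 0) stop("step window contains no EMG samples")
          if (stat == "mean") mean(w) else sqrt(mean(w^2))
        }, numeric(1))
        out[key] <- mean(per_step)
      }
    }
  }
  out[sort(names(out))]
}

#' Envelope peak detection
#'
#' Finds local maxima of a normalized envelope with amplitude at least
#' `min_height` (fraction of MVC) and duration at least `min_width_s`.
#' Duration is measured, per the package's convention, as the width of the
#' contiguous region where the envelope stays above the peak height minus
#' half the peak's prominence (crossings located by linear interpolation).
#' An alternative `"above_threshold"` mode measures the contiguous
#' supra-`min_height` region containing the peak instead.
#'
#' @param x Numeric envelope vector.
#' @param fs Sampling rate, Hz.
#' @param min_height Minimum peak amplitude (default 0.10 of MVC).
#' @param min_width_s Minimum duration in seconds (default 0.2).
#' @param duration_mode `"half_prominence"` (default) or
#'   `"above_threshold"`.
#' @return data.frame with `index`, `time_s`, `amplitude`, `prominence`,
#'   `duration_s` for each qualifying peak.
#' @export
find_envelope_peaks <- function(x, fs, min_height = 0.10, min_width_s = 0.2,
                                duration_mode = c("half_prominence", "above_threshold")) {
  duration_mode <- match.arg(duration_mode)
  n <- length(x)
  if (n < 3) {
    return(data.frame(
      index = integer(0), time_s = numeric(0), amplitude = numeric(0),
      prominence = numeric(0), duration_s = numeric(0)
    ))
  }
  # local maxima with plateau handling: midpoint of each flat top
  peaks <- integer(0)
  i <- 2
  while (i < n) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[j]) j <- j + 1
      if (j < n && x[j + 1] < x[j]) {
        peaks <- c(peaks, (i + j) %/% 2)
        i <- j + 1
        next
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  peaks <- peaks[x[peaks] >= min_height]
  if (length(peaks) == 0) {
    return(data.frame(
      index = integer(0), time_s = numeric(0), amplitude = numeric(0),
      prominence = numeric(0), duration_s = numeric(0)
    ))
  }
  prom <- vapply(peaks, function(p) peak_prominence(x, p), numeric(1))
  dur <- vapply(seq_along(peaks), function(k) {
    p <- peaks[k]
    if (duration_mode == "half_prominence") {
      peak_width(x, p, x[p] - prom[k] / 2) / fs
    } else {
      peak_width(x, p, min_height) / fs
    }
  }, numeric(1))
  keep <- dur >= min_width_s
  data.frame(
    index = peaks[keep], time_s = (peaks[keep] - 1) / fs,
    amplitude = x[peaks[keep]], prominence = prom[keep],
    duration_s = dur[keep]
  )
}

# topographic prominence: height above the higher of the two lowest points
# separating the peak from higher terrain (or the signal boundary)
peak_prominence <- function(x, p) {
  h <- x[p]
  i <- p
  left_min <- h
  while (i > 1) {
    i <- i - 1
    if (x[i] > h) break
    if (x[i] < left_min) left_min <- x[i]
  }
  i <- p
  right_min <- h
  n <- length(x)
  while (i < n) {
    i <- i + 1
    if (x[i] > h) break
    if (x[i] < right_min) right_min <- x[i]
  }
  h - max(left_min, right_min)
}

# width (in samples) of the region around peak p where x stays above
# `level`, with linearly interpolated boundary crossings
peak_width <- function(x, p, level) {
  n <- length(x)
  i <- p
  while (i > 1 && x[i - 1] > level) i <- i - 1
  left <- if (i == 1 || x[i - 1] == x[i]) {
    i
  } else {
    i - (level - x[i]) / (x[i - 1] - x[i])
  }
  j <- p
  while (j < n && x[j + 1] > level) j <- j + 1
  right <- if (j == n || x[j + 1] == x[j]) {
    j
  } else {
    j + (x[j] - level) / (x[j] - x[j + 1])
  }
  right - left
}

#' The 2 peak-median EMG features of a trial
#'
#' Peak detection on each unsegmented normalized envelope channel
#' (including the standstill padding), keeping peaks with amplitude of at
#' least 10% of MVC and duration of at least 0.2 s; the feature is the
#' median of the qualifying peak amplitudes (0 when no peak qualifies).
#'
#' @inheritParams trial_emg_step_features
#' @inheritParams find_envelope_peaks
#' @return Named numeric vector `c("ES_L|peakmedian", "ES_R|peakmedian")`.
#' @export
trial_emg_peak_features <- function(env, min_height = 0.10, min_width_s = 0.2,
                                    duration_mode = "half_prominence") {
  stopifnot(inherits(env, "emg_envelope"))
  out <- numeric(0)
  for (m in c("ES_L", "ES_R")) {
    pk <- find_envelope_peaks(env$envelope[, m], env$fs,
      min_height = min_height,
      min_width_s = min_width_s, duration_mode = duration_mode
    )
    out[paste0(m, "|peakmedian")] <- if (nrow(pk) == 0) 0 else stats::median(pk$amplitude)
  }
  out
}

#' The 10 EMG features of one trial
#'
#' Combines the 8 step-based features with the 2 peak-median features. A
#' missing EMG recording yields all-zero features with
#' `missing_emg = TRUE`.
#'
#' @param emg An [emg_recording()] with role `"trial"`, or `NULL`.
#' @param mvc_ref Per-muscle MVC reference from [mvc_reference()].
#' @param steps Step windows from [segment_steps()].
#' @return List with `values` (named numeric vector of length 10, names
#'   from [emg_feature_names()]) and `missing_emg` (logical).
#' @export
trial_emg_features <- function(emg, mvc_ref, steps) {
  nm <- emg_feature_names()
  if (is.null(emg)) {
    return(list(values = stats::setNames(rep(0, length(nm)), nm), missing_emg = TRUE))
  }
  env <- normalize_envelope(preprocess_emg(emg), mvc_ref)
  values <- c(trial_emg_step_features(env, steps), trial_emg_peak_features(env))
  list(values = values[nm], missing_emg = FALSE)
}
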