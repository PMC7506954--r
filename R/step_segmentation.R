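#' Segment a heel-strike event stream into left and right steps
#'
#' Each consecutive pair of alternating heel strikes bounds one step: a
#' left-then-right pair is a *right* step and a right-then-left pair a
#' *left* step (the step is named after the foot that lands at its end).
#' Windows are half-open `[start, end)` so every sample belongs to exactly
#' one step; data before the first and after the last heel strike belong
#' to no step. Consecutive events on the same side — possible with
#' imperfect detection — are skipped with a warning rather than treated as
#' fatal.
#'
#' @param heel_strikes data.frame with `time_s` (strictly increasing) and
#'   `side` (`"L"`/`"R"`).
#' @return data.frame with `start_s`, `end_s`, `side`; zero rows if no
#'   alternating pair exists.
#' @examples
#' segment_steps(data.frame(time_s = c(0, 0.55, 1.1), side = c("L", "R", "L")))
#' @export
segment_steps <- function(heel_strikes) {
  validate_heel_strikes(heel_strikes)
  n <- nrow(heel_strikes)
  if (n < 2) stop("insufficient events: step segmentation needs at least 2 heel strikes")
  from <- heel_strikes[-n, ]
  to <- heel_strikes[-1, ]
  ok <- from$side != to$side
  if (any(!ok)) {
    warning(sum(!ok), " same-side consecutive heel-strike pair(s) skipped")
  }
  out <- data.frame(
    start_s = from$time_s[ok],
    end_s = to$time_s[ok],
    side = to$side[ok]
  )
  rownames(out) <- NULL
  out
}
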