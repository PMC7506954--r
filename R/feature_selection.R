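# Sequential floating forward selection (SFFS) driven by partial-F
# p-values within an ordinary least-squares model of the numeric class
# code, with the adaptive 0.05 -> 0.01 -> 0.001 threshold scheme and a
# 50-feature cap.
#
# The inclusion criterion for a candidate given the selected block is the
# partial-F test of adding it to the OLS model (intercept + selected):
#   F = (RSS0 - RSS1) / (RSS1 / (n - q - 2)),  F ~ F(1, n - q - 2)
# with q the number of already-selected features. The exclusion criterion
# for a selected feature is its partial-F p-value in the current model
# (equivalently the square of its t statistic). Candidates collinear with
# the selected block, or constant, get p = 1.

REL_RANK_TOL <- 1e-10

#' Partial-F p-value of one candidate feature
#'
#' The p-value for adding `candidate` to an ordinary least-squares model
#' of the numeric class code on the already-selected features plus an
#' intercept. A constant candidate, or one collinear with the selected
#' block (relative residual sum of squares below `1e-10`), returns 1;
#' a perfect fit returns 0.
#'
#' @param selected_block Numeric matrix of already-selected feature
#'   columns (or `NULL`/zero-column matrix for an empty set).
#' @param candidate Numeric vector, the candidate feature column.
#' @param labels Integer class codes (>= 2 distinct values).
#' @return A p-value in `[0, 1]`.
#' @export
candidate_pvalue <- function(selected_block, candidate, labels) {
  if (is.null(selected_block)) selected_block <- matrix(numeric(0), length(labels), 0)
  p <- candidate_pvalues_block(
    as.matrix(selected_block),
    matrix(candidate, ncol = 1), as.numeric(labels)
  )
  p[1]
}

# vectorized partial-F p-values for every column of `candidates`
candidate_pvalues_block <- function(selected_block, candidates, y) {
  n <- length(y)
  q <- ncol(selected_block)
  if (length(unique(y)) < 2) stop("labels must have at least 2 distinct values")
  df2 <- n - q - 2
  if (df2 < 1) stop("degenerate problem: need n > |selected| + 2 trials")
  D <- cbind(1, selected_block)
  Q <- qr.Q(qr(D))
  r_y <- y - Q %*% crossprod(Q, y)
  RSS0 <- sum(r_y^2)
  SST <- sum((y - mean(y))^2)
  Rc <- candidates - Q %*% crossprod(Q, candidates)
  d <- colSums(Rc^2)
  ss_c <- colSums(scale(candidates, scale = FALSE)^2)
  s <- drop(crossprod(Rc, r_y))
  RSS1 <- pmax(0, RSS0 - s^2 / ifelse(d > 0, d, Inf))
  F_stat <- (RSS0 - RSS1) * df2 / RSS1
  p <- stats::pf(F_stat, 1, df2, lower.tail = FALSE)
  p[RSS1 <= REL_RANK_TOL * SST] <- 0 # (near-)perfect fit after adding
  degenerate <- ss_c <= 0 | d <= REL_RANK_TOL * ss_c
  p[degenerate] <- 1
  if (RSS0 <= REL_RANK_TOL * SST) p[] <- 1 # model already perfect
  p
}

# removal p-values of every selected feature in the current OLS model
# (partial F on 1 and n - q - 1 df, via t statistics)
removal_pvalues <- function(X_sel, y) {
  n <- length(y)
  q <- ncol(X_sel)
  D <- cbind(`(intercept)` = 1, X_sel)
  fit <- stats::lm.fit(D, y)
  df <- n - q - 1
  rss <- sum(fit$residuals^2)
  XtXi <- tryCatch(chol2inv(chol(crossprod(D))), error = function(e) NULL)
  if (is.null(XtXi)) {
    # numerically singular selected block: every member is redundant
    return(stats::setNames(rep(1, q), colnames(X_sel)))
  }
  se <- sqrt(pmax(diag(XtXi), 0) * rss / df)
  tval <- ifelse(se > 0, fit$coefficients / se, Inf)
  p <- 2 * stats::pt(-abs(tval), df)
  if (rss <= REL_RANK_TOL * sum((y - mean(y))^2)) p[] <- 0
  stats::setNames(p[-1], colnames(X_sel))
}

#' Sequential floating forward selection
#'
#' Starting from the empty set, repeatedly adds the unselected feature
#' with the smallest partial-F p-value if it is below `p_in`; after each
#' inclusion, conditionally removes selected features whose removal
#' p-value exceeds `p_out` (worst first, repeated until none qualifies,
#' never removing the feature added in the same floating pass). Stops when
#' no candidate meets `p_in`. Fully deterministic: ties are broken by
#' canonical (column) order.
#'
#' @param X Numeric feature matrix with unique column names.
#' @param labels Integer class codes.
#' @param threshold Inclusion threshold `p_in` (exclusion `p_out` defaults
#'   to the same value).
#' @param p_out Exclusion threshold.
#' @param max_features Hard cap on the selected-set size (defaults to
#'   `n - 4`, keeping the partial-F test well defined).
#' @return A list of class `selection_result`: `selected` (ordered names),
#'   `inclusion_p`, `threshold_used`, `n_candidates` and `history`
#'   (data.frame of add/remove actions).
#' @export
sffs <- function(X, labels, threshold = 0.05, p_out = threshold,
                 max_features = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) || anyDuplicated(colnames(X))) {
    stop("X must have unique column names")
  }
  y <- as.numeric(labels)
  n <- nrow(X)
  if (is.null(max_features)) max_features <- n - 4
  max_features <- min(max_features, n - 4)
  selected <- character(0)
  inclusion_p <- numeric(0)
  history <- list()
  max_iter <- 2000L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      warning("SFFS stopped after ", max_iter, " iterations without converging")
      break
    }
    if (length(selected) >= max_features) break
    candidates <- setdiff(colnames(X), selected)
    if (length(candidates) == 0) break
    p <- candidate_pvalues_block(
      X[, selected, drop = FALSE],
      X[, candidates, drop = FALSE], y
    )
    best <- which.min(p) # first minimum = canonical-order tie-break
    if (p[best] >= threshold) break
    added <- candidates[best]
    selected <- c(selected, added)
    inclusion_p <- c(inclusion_p, p[best])
    history[[length(history) + 1]] <- data.frame(
      action = "add", feature = added, p_value = p[best]
    )
    # floating pass: conditional exclusion, sparing the feature just added
    repeat {
      removable <- setdiff(selected, added)
      if (length(removable) == 0) break
      rp <- removal_pvalues(X[, selected, drop = FALSE], y)[removable]
      worst <- max(rp)
      if (worst <= p_out) break
      drop_ft <- removable[which(rp == worst)][1]
      keep <- selected != drop_ft
      history[[length(history) + 1]] <- data.frame(
        action = "remove", feature = drop_ft, p_value = worst
      )
      inclusion_p <- inclusion_p[keep]
      selected <- selected[keep]
    }
  }
  structure(
    list(
      selected = selected,
      inclusion_p = stats::setNames(inclusion_p, selected),
      threshold_used = threshold,
      n_candidates = ncol(X),
      history = if (length(history)) do.call(rbind, history) else
        data.frame(action = character(0), feature = character(0), p_value = numeric(0))
    ),
    class = "selection_result"
  )
}

#' Adaptive-threshold floating feature selection
#'
#' Runs [sffs()] at `p = 0.05`; if more than 50 features are selected the
#' run is discarded and selection restarts from scratch at `p = 0.01`, and
#' if still over 50, at `p = 0.001` (whose result is kept regardless).
#' This guards against overfitting on wide feature matrices.
#'
#' @inheritParams sffs
#' @param thresholds Decreasing threshold ladder.
#' @param max_selected Set-size cap that triggers the next rung (50).
#' @return A `selection_result` with `threshold_used` recorded.
#' @export
adaptive_select <- function(X, labels, thresholds = c(0.05, 0.01, 0.001),
                            max_selected = 50) {
  res <- NULL
  for (th in thresholds) {
    res <- sffs(X, labels, threshold = th)
    if (length(res$selected) <= max_selected) break
  }
  res
}

#' @export
print.selection_result <- function(x, ...) {
  cat(
    "<selection_result>", length(x$selected), "of", x$n_candidates,
    "features at p <", format(x$threshold_used), "\n"
  )
  if (length(x$selected)) {
    cat(
      " top:", paste(utils::head(x$selected, 5), collapse = "; "),
      if (length(x$selected) > 5) "..." else "", "\n"
    )
  }
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' @param result A `selection_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  doc <- list(
    format_version = "1.0",
    threshold_used = result$threshold_used,
    n_candidates = result$n_candidates,
    selected = result$selected,
    inclusion_p = unname(result$inclusion_p),
    history = result$history
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
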