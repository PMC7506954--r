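# The four classifiers and leave-participant-out cross-validation.
#
# All classifiers consume a numeric feature matrix (z-scored by the
# caller with training-fold statistics) and integer class codes 1..K:
#   REG - ordinary least squares on the class code; the continuous
#         prediction is rounded half-up to the nearest code and clipped
#         to [1, K] ("regression-rounded" classifier)
#   LDA - linear discriminant analysis with pooled covariance,
#         ridge-regularized by a 1e-6 trace fraction if singular
#   SVM - linear-kernel support vector machine, cost 1, one-vs-one for
#         K > 2 (via e1071/libsvm)
#   EDT - bagged ensemble of 100 depth-unlimited trees with a fixed seed
#         (via randomForest with mtry = p, i.e. plain bagging)

CLASSIFIERS <- c("REG", "LDA", "SVM", "EDT")

#' Train a classifier on integer class codes
#'
#' @param X Numeric feature matrix (rows = trials).
#' @param y_codes Integer class codes in `1..K`.
#' @param method One of `"REG"`, `"LDA"`, `"SVM"`, `"EDT"`.
#' @param K Number of classes (defaults to `max(y_codes)`).
#' @param seed Seed for the stochastic EDT ensemble (ignored by the
#'   deterministic classifiers).
#' @return A model object of class `carrygait_model`.
#' @export
fit_classifier <- function(X, y_codes, method = CLASSIFIERS, K = max(y_codes), seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y_codes <- as.integer(y_codes)
  if (length(unique(y_codes)) < 2) stop("single-class training labels")
  fit <- switch(method,
    REG = fit_reg(X, y_codes),
    LDA = fit_lda(X, y_codes),
    SVM = e1071::svm(
      x = X, y = factor(y_codes, levels = seq_len(K)),
      kernel = "linear", cost = 1, scale = FALSE
    ),
    EDT = with_seed(seed, randomForest::randomForest(
      x = X, y = factor(y_codes, levels = seq_len(K)),
      ntree = 100, mtry = ncol(X), replace = TRUE
    ))
  )
  structure(list(method = method, K = K, fit = fit, seed = seed),
    class = "carrygait_model"
  )
}

#' Predict class codes
#'
#' @param model A `carrygait_model` from [fit_classifier()].
#' @param X Feature matrix on the same scale as the training matrix.
#' @return Integer class codes in `1..K`.
#' @export
predict_classes <- function(model, X) {
  stopifnot(inherits(model, "carrygait_model"))
  X <- as.matrix(X)
  switch(model$method,
    REG = {
      yhat <- drop(cbind(1, X) %*% model$fit$coefficients)
      round_to_class(yhat, model$K)
    },
    LDA = predict_lda(model$fit, X),
    SVM = as.integer(as.character(stats::predict(model$fit, X))),
    EDT = with_seed(
      model$seed + 1L,
      as.integer(as.character(stats::predict(model$fit, X)))
    )
  )
}

# round half-up to the nearest class code, clipped to [1, K]
round_to_class <- function(yhat, K) {
  pmin(pmax(as.integer(floor(yhat + 0.5)), 1L), as.integer(K))
}

# OLS with intercept; rank-deficient designs fall back to the
# minimum-norm solution (SVD pseudoinverse) with a warning
fit_reg <- function(X, y) {
  D <- cbind(1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("rank-deficient regression design: using the minimum-norm solution")
    sv <- svd(D)
    pos <- sv$d > max(sv$d) * 1e-10
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  } else {
    coef <- qr.coef(qrD, y)
  }
  list(coefficients = drop(coef))
}

# LDA with pooled within-class covariance and empirical priors
fit_lda <- function(X, y) {
  classes <- sort(unique(y))
  p <- ncol(X)
  n <- nrow(X)
  means <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]), numeric(p)))
  S <- matrix(0, p, p)
  for (k in classes) {
    Xk <- X[y == k, , drop = FALSE]
    if (nrow(Xk) > 1) {
      Xc <- sweep(Xk, 2, colMeans(Xk))
      S <- S + crossprod(Xc)
    }
  }
  S <- S / (n - length(classes))
  Sinv <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
  if (is.null(Sinv)) {
    ridge <- 1e-6 * sum(diag(S)) / p
    if (ridge <= 0) ridge <- 1e-8
    Sinv <- chol2inv(chol(S + diag(ridge, p)))
  }
  priors <- vapply(classes, function(k) mean(y == k), numeric(1))
  list(classes = classes, means = means, Sinv = Sinv, log_priors = log(priors))
}

predict_lda <- function(fit, X) {
  # linear discriminant scores d_k(x) = x' Sinv mu_k - mu_k' Sinv mu_k / 2 + log pi_k
  W <- fit$Sinv %*% t(fit$means) # p x K
  b <- -0.5 * colSums(t(fit$means) * W) + fit$log_priors
  scores <- X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE)
  fit$classes[max.col(scores, ties.method = "first")]
}

#' Leave-participant-out cross-validation of one classification cell
#'
#' Maps each trial to its class under `problem` (excluding skipped
#' conditions), restricts columns to the chosen feature set, selects
#' features, and evaluates the classifier with one fold per participant:
#' the fold's participant is the test set, all others train. Features are
#' z-scored with training-fold statistics (zero-variance columns are left
#' unscaled). Train/test participant disjointness is asserted in every
#' fold.
#'
#' Feature selection scope: `"pooled"` (default) selects once on the full
#' dataset before cross-validation, mirroring protocols that report a
#' single selected-feature count; `"per_fold"` re-runs selection inside
#' each training fold and is free of selection leakage. Both are reported
#' by [pipeline_report()].
#'
#' @param features A `trial_features` data.frame ([cohort_features()]).
#' @param problem Problem id (`"P1"`..`"P5"`) or definition.
#' @param feature_set `"inertial"`, `"emg"` or `"both"`.
#' @param classifier One of `"REG"`, `"LDA"`, `"SVM"`, `"EDT"`.
#' @param selection_mode `"pooled"` or `"per_fold"`.
#' @param selection Optional precomputed `selection_result` to reuse
#'   (pooled mode only).
#' @param seed Seed for stochastic classifiers.
#' @return A list of class `cv_result`: fold accuracies (per participant,
#'   percent), `mean_accuracy`, a K x K `confusion` matrix (rows = true),
#'   and the selection record.
#' @export
lopo_cv <- function(features, problem, feature_set = c("both", "inertial", "emg"),
                    classifier = CLASSIFIERS,
                    selection_mode = c("pooled", "per_fold"),
                    selection = NULL, seed = 1L) {
  feature_set <- match.arg(feature_set)
  classifier <- match.arg(classifier)
  selection_mode <- match.arg(selection_mode)
  problem <- resolve_problem(problem)
  K <- length(problem$classes)

  cond <- load_conditions()
  cond_rows <- match(features$condition_id, cond$condition_id)
  if (anyNA(cond_rows)) stop("feature matrix contains unknown condition ids")
  labels <- label_condition(cond[cond_rows, ], problem)
  keep <- !is.na(labels)
  y <- class_codes(labels[keep], problem)
  pid <- features$participant_id[keep]
  X_all <- feature_block(features, feature_set)[keep, , drop = FALSE]

  participants <- unique(pid)
  if (length(participants) < 2) stop("leave-participant-out CV needs at least 2 participants")

  if (selection_mode == "pooled" && is.null(selection)) {
    selection <- adaptive_select(X_all, y)
  }

  fold_acc <- stats::setNames(numeric(length(participants)), participants)
  confusion <- matrix(0L, K, K, dimnames = list(true = problem$classes, predicted = problem$classes))
  fold_selections <- if (selection_mode == "per_fold") vector("list", length(participants))
  for (f in seq_along(participants)) {
    test_pid <- participants[f]
    tr <- pid != test_pid
    te <- !tr
    stopifnot(length(intersect(unique(pid[tr]), unique(pid[te]))) == 0) # no leakage
    if (sum(te) == 0) stop("empty test fold for participant ", test_pid)
    sel <- if (selection_mode == "pooled") {
      selection
    } else {
      fold_selections[[f]] <- adaptive_select(X_all[tr, , drop = FALSE], y[tr])
      fold_selections[[f]]
    }
    if (length(sel$selected) == 0) {
      # degenerate empty selection: fall back to the training majority class
      maj <- as.integer(names(which.max(table(y[tr])))[1])
      pred <- rep(maj, sum(te))
    } else {
      Xtr <- X_all[tr, sel$selected, drop = FALSE]
      Xte <- X_all[te, sel$selected, drop = FALSE]
      mu <- colMeans(Xtr)
      sd_ <- apply(Xtr, 2, stats::sd)
      sd_[sd_ == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sd_, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sd_, "/")
      model <- fit_classifier(Xtr, y[tr], classifier, K = K, seed = seed + f)
      pred <- predict_classes(model, Xte)
    }
    fold_acc[f] <- 100 * mean(pred == y[te])
    for (i in seq_along(pred)) {
      confusion[y[te][i], pred[i]] <- confusion[y[te][i], pred[i]] + 1L
    }
  }
  structure(
    list(
      problem_id = problem$problem_id, classes = problem$classes,
      feature_set = feature_set, classifier = classifier,
      selection_mode = selection_mode,
      fold_accuracies = fold_acc,
      mean_accuracy = mean(fold_acc),
      confusion = confusion,
      selection = if (selection_mode == "pooled") selection else fold_selections,
      n_trials = length(y)
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(
    "<cv_result>", x$problem_id, "/", x$feature_set, "/", x$classifier,
    ":", sprintf("%.1f%%", x$mean_accuracy), "over",
    length(x$fold_accuracies), "folds\n"
  )
  invisible(x)
}
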