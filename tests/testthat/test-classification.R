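test_that("regression-rounded predictions use round-half-up with clipping", {
  model <- structure(
    list(method = "REG", K = 3, fit = list(coefficients = c(0, 1)), seed = 1L),
    class = "carrygait_model"
  )
  expect_equal(
    predict_classes(model, matrix(c(0.2, 1.4, 2.5, 3.7), ncol = 1)),
    c(1L, 1L, 3L, 3L)
  )
})

test_that("regression coefficients match the normal-equations oracle", {
  set.seed(701)
  for (i in 1:100) {
    X <- matrix(stats::rnorm(30 * 5), 30)
    y <- sample(1:3, 30, replace = TRUE)
    m <- fit_classifier(X, y, "REG")
    expect_equal(unname(m$fit$coefficients), unname(oracle_ols(X, y)), tolerance = 1e-8)
  }
})

test_that("a rank-deficient regression design warns and still predicts", {
  set.seed(702)
  X <- matrix(stats::rnorm(20 * 3), 20)
  X <- cbind(X, X[, 1]) # exact collinearity
  y <- rep(1:2, each = 10)
  expect_warning(m <- fit_classifier(X, y, "REG"), "rank-deficient")
  expect_true(all(predict_classes(m, X) %in% 1:2))
})

test_that("all four classifiers separate well-separated Gaussian classes", {
  set.seed(703)
  n <- 100
  y <- rep(1:2, each = n / 2)
  X <- matrix(stats::rnorm(n * 4), n) + outer(ifelse(y == 1, -3, 3), c(1, 1, 0, 0))
  for (cl in c("REG", "LDA", "SVM", "EDT")) {
    m <- fit_classifier(X, y, cl, seed = 5)
    expect_gte(mean(predict_classes(m, X) == y), 0.99)
  }
  expect_error(fit_classifier(X, rep(1, n), "LDA"), "single-class")
})

test_that("a 1-D noiseless two-class toy is fit perfectly by regression", {
  X <- matrix(rep(c(-1, 1), each = 10), ncol = 1)
  y <- rep(1:2, each = 10)
  m <- fit_classifier(X, y, "REG")
  expect_equal(predict_classes(m, X), y)
})

test_that("the in-package LDA agrees with an independent implementation", {
  set.seed(704)
  for (i in 1:20) {
    n <- 90
    y <- rep(1:3, each = n / 3)
    X <- matrix(stats::rnorm(n * 5), n) + outer(y, c(2, -1, 0.5, 0, 1))
    m <- fit_classifier(X, y, "LDA")
    ref <- MASS::lda(X, grouping = factor(y))
    got <- predict_classes(m, X)
    want <- as.integer(as.character(stats::predict(ref, X)$class))
    expect_gte(mean(got == want), 0.98)
  }
})

test_that("the bagged tree ensemble is seed-deterministic", {
  set.seed(705)
  n <- 60
  y <- rep(1:2, each = n / 2)
  X <- matrix(stats::rnorm(n * 6), n) + outer(ifelse(y == 1, -1, 1), rep(1, 6))
  m1 <- fit_classifier(X, y, "EDT", seed = 42)
  m2 <- fit_classifier(X, y, "EDT", seed = 42)
  Xnew <- matrix(stats::rnorm(40 * 6), 40)
  expect_identical(predict_classes(m1, Xnew), predict_classes(m2, Xnew))
})

test_that("LOPO CV has one fold per participant and consistent bookkeeping", {
  feat <- tiny_features()
  res <- lopo_cv(feat, "P1", "inertial", "REG", seed = 1)
  expect_equal(sort(names(res$fold_accuracies)), sort(unique(feat$participant_id)))
  expect_true(all(res$fold_accuracies >= 0 & res$fold_accuracies <= 100))
  expect_equal(res$mean_accuracy, mean(res$fold_accuracies))
  # confusion rows sum to the per-class trial counts over all folds
  expect_equal(unname(rowSums(res$confusion)), unname(class_counts("P1")) * 2)
  expect_equal(sum(res$confusion), res$n_trials)
  # skipped conditions are excluded before folding
  res3 <- lopo_cv(feat, "P3", "inertial", "REG", seed = 1)
  expect_equal(res3$n_trials, 16 * 2)
})

test_that("an empty selection falls back to the training majority class", {
  feat <- tiny_features()
  empty_sel <- structure(
    list(
      selected = character(0), inclusion_p = numeric(0),
      threshold_used = 0.05, n_candidates = 528,
      history = data.frame()
    ),
    class = "selection_result"
  )
  res <- lopo_cv(feat, "P1", "inertial", "REG", selection = empty_sel, seed = 1)
  # majority class ("no box", 16/19) predicted everywhere
  expect_equal(res$mean_accuracy, 100 * 16 / 19, tolerance = 1e-9)
})

test_that("removing the box posture effect removes the box classifiability", {
  with_effect <- lopo_cv(
    cached_features(3, default_config(21)), "P1", "inertial", "REG",
    seed = 1
  )
  without <- lopo_cv(
    cached_features(3, null_config(21)), "P1", "inertial", "REG",
    seed = 1
  )
  expect_equal(with_effect$mean_accuracy, 100)
  expect_lt(without$mean_accuracy, with_effect$mean_accuracy)
})

test_that("reports summarize cells and top features", {
  feat <- tiny_features()
  r1 <- lopo_cv(feat, "P1", "inertial", "REG", seed = 1)
  r2 <- lopo_cv(feat, "P1", "emg", "SVM", seed = 1)
  rep_ <- pipeline_report(list(r1, r2))
  expect_equal(nrow(rep_$cells), 2)
  expect_equal(rep_$summary$inertial_accuracy, r1$mean_accuracy)
  expect_equal(rep_$summary$emg_accuracy, r2$mean_accuracy)
  expect_true(is.na(rep_$summary$both_accuracy))
  expect_equal(rep_$top_features$P1, utils::head(r1$selection$selected, 5))
  # empty report renders headers only
  empty <- pipeline_report(list())
  expect_equal(nrow(empty$cells), 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep_, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(doc$cells), 2)
})
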