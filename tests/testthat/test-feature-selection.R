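test_that("candidate p-values handle the degenerate cases", {
  set.seed(601)
  n <- 30
  y <- rep(1:3, each = 10)
  x <- stats::rnorm(n)
  # a candidate identical to an already-selected feature adds nothing
  expect_equal(candidate_pvalue(matrix(x, ncol = 1), x, y), 1)
  # affine transforms of a selected feature are collinear too
  expect_equal(candidate_pvalue(matrix(x, ncol = 1), 2 * x - 5, y), 1)
  # a constant candidate adds nothing
  expect_equal(candidate_pvalue(NULL, rep(3, n), y), 1)
  # a candidate equal to the label codes fits perfectly
  expect_lt(candidate_pvalue(NULL, as.numeric(y), y), 1e-12)
  expect_error(candidate_pvalue(NULL, x, rep(1, n)), "distinct")
  expect_error(
    candidate_pvalue(matrix(stats::rnorm(5 * 4), 5), stats::rnorm(5), c(1, 1, 2, 2, 1)),
    "degenerate"
  )
})

test_that("candidate p-values match the OLS partial-F oracle", {
  set.seed(602)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    q <- sample(0:4, 1)
    Xs <- if (q > 0) matrix(stats::rnorm(n * q), n) else NULL
    cand <- stats::rnorm(n)
    y <- sample(1:3, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    got <- candidate_pvalue(Xs, cand, y)
    want <- oracle_partial_f(Xs, cand, y)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("SFFS recovers a planted informative feature first", {
  set.seed(603)
  n <- 60
  y <- rep(1:3, each = n / 3)
  X <- matrix(stats::rnorm(n * 100), n)
  colnames(X) <- sprintf("f%03d", seq_len(100))
  X[, "f042"] <- y + stats::rnorm(n, sd = 0.05)
  res <- sffs(X, y, threshold = 0.05)
  expect_equal(res$selected[1], "f042")
  expect_lt(res$inclusion_p[1], 1e-10)
  expect_true(all(res$inclusion_p < 0.05))
})

test_that("duplicated informative columns: exactly one of the pair is kept", {
  set.seed(604)
  n <- 60
  y <- rep(1:2, each = n / 2)
  X <- matrix(stats::rnorm(n * 20), n)
  colnames(X) <- sprintf("f%02d", seq_len(20))
  inf <- y + stats::rnorm(n, sd = 0.3)
  X[, "f03"] <- inf
  X[, "f17"] <- inf # exact duplicate
  res <- sffs(X, y, threshold = 0.05)
  expect_equal(sum(c("f03", "f17") %in% res$selected), 1)
  # canonical-order tie-break picks the earlier column
  expect_true("f03" %in% res$selected)
})

test_that("SFFS is deterministic and its fixed point respects p_out", {
  set.seed(605)
  n <- 80
  y <- sample(1:3, n, replace = TRUE)
  X <- matrix(stats::rnorm(n * 40), n)
  colnames(X) <- sprintf("g%02d", seq_len(40))
  X[, 1] <- y + stats::rnorm(n, sd = 0.5)
  X[, 2] <- y + stats::rnorm(n, sd = 0.8)
  r1 <- sffs(X, y, threshold = 0.05)
  r2 <- sffs(X, y, threshold = 0.05)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$history, r2$history)
  if (length(r1$selected) > 1) {
    # floating fixed point: no remaining member is removable at p_out
    rp <- carrygait:::removal_pvalues(X[, r1$selected, drop = FALSE], y)
    expect_true(all(rp <= 0.05 + 1e-12))
  }
})

test_that("on pure noise the strictest threshold keeps the set tiny", {
  set.seed(606)
  sizes <- integer(20)
  for (i in seq_along(sizes)) {
    n <- 190
    y <- sample(1:3, n, replace = TRUE)
    X <- matrix(stats::rnorm(n * 100), n)
    colnames(X) <- sprintf("n%03d", seq_len(100))
    sizes[i] <- length(sffs(X, y, threshold = 0.001)$selected)
  }
  expect_gte(mean(sizes <= 2), 0.95)
})

test_that("the adaptive ladder lowers the threshold only when a run overflows", {
  set.seed(607)
  n <- 120
  y <- rep(1:2, each = n / 2)
  # many moderately informative, mutually correlated columns: the 0.05 run
  # overflows the 50-feature cap, the 0.01 rerun does not
  base <- y + stats::rnorm(n, sd = 2.5)
  X <- sapply(seq_len(160), function(i) base + stats::rnorm(n, sd = 1.5))
  colnames(X) <- sprintf("c%03d", seq_len(160))
  r05 <- sffs(X, y, threshold = 0.05)
  res <- adaptive_select(X, y)
  if (length(r05$selected) > 50) {
    expect_lt(res$threshold_used, 0.05)
    expect_lte(length(res$selected), 50)
  } else {
    expect_equal(res$threshold_used, 0.05)
  }
  # all-noise data never overflows the first rung
  Xn <- matrix(stats::rnorm(n * 120), n)
  colnames(Xn) <- sprintf("z%03d", seq_len(120))
  rn <- adaptive_select(Xn, sample(1:3, n, replace = TRUE))
  expect_equal(rn$threshold_used, 0.05)
  expect_lt(length(rn$selected), 25)
})

test_that("selection results serialize to JSON", {
  set.seed(608)
  n <- 40
  y <- rep(1:2, each = 20)
  X <- matrix(stats::rnorm(n * 10), n)
  colnames(X) <- sprintf("s%02d", seq_len(10))
  X[, 4] <- y
  res <- sffs(X, y, 0.05)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_json(res, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$selected, res$selected)
  expect_equal(doc$threshold_used, 0.05)
})
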