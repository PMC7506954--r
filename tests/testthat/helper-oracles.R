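# Independent brute-force oracles used to cross-check the package's
# numerical routines. Deliberately written with different algorithms /
# primitives than the implementation.

# two-pass textbook moments
oracle_moments <- function(w) {
  n <- length(w)
  m <- sum(w) / n
  v <- if (n > 1) sum((w - m)^2) / (n - 1) else 0
  ma <- sum(abs(w)) / n
  va <- if (n > 1) sum((abs(w) - ma)^2) / (n - 1) else 0
  c(mean = m, var = v, mean_abs = ma, var_abs = va)
}

# normal-equations least squares
oracle_ols <- function(X, y) {
  D <- cbind(1, X)
  drop(solve(t(D) %*% D, t(D) %*% y))
}

# partial-F p-value via R's model-comparison machinery
oracle_partial_f <- function(X_sel, cand, y) {
  if (is.null(X_sel) || ncol(as.matrix(X_sel)) == 0) {
    fit0 <- stats::lm(y ~ 1)
  } else {
    fit0 <- stats::lm(y ~ as.matrix(X_sel))
  }
  fit1 <- stats::update(fit0, . ~ . + cand)
  stats::anova(fit0, fit1)[2, "Pr(>F)"]
}

# reference peak scan: all strict local maxima, topographic prominence by
# explicit whole-range min/max, width at (height - prominence/2) with
# linear interpolation
oracle_peaks <- function(x, fs, min_height = 0.10, min_width_s = 0.2) {
  n <- length(x)
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] < 0) + 1L
  # plateau maxima: runs of equal values with rise before and fall after
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$lengths[k] > 1 && starts[k] > 1 && ends[k] < n &&
      x[starts[k] - 1] < r$values[k] && x[ends[k] + 1] < r$values[k]) {
      cand <- c(cand, (starts[k] + ends[k]) %/% 2)
    }
  }
  cand <- sort(unique(cand))
  cand <- cand[x[cand] >= min_height]
  rows <- lapply(cand, function(p) {
    h <- x[p]
    higher_left <- which(x[seq_len(p - 1)] > h)
    lo_l <- if (length(higher_left)) min(x[(max(higher_left) + 1):(p - 1)]) else min(x[seq_len(p)])
    higher_right <- which(x[(p + 1):n] > h) + p
    lo_r <- if (length(higher_right)) min(x[(p + 1):(min(higher_right) - 1)]) else min(x[p:n])
    prom <- h - max(lo_l, lo_r)
    lev <- h - prom / 2
    i <- p
    while (i > 1 && x[i - 1] > lev) i <- i - 1
    left <- if (i == 1 || x[i - 1] == x[i]) i else i - (lev - x[i]) / (x[i - 1] - x[i])
    j <- p
    while (j < n && x[j + 1] > lev) j <- j + 1
    right <- if (j == n || x[j + 1] == x[j]) j else j + (x[j] - lev) / (x[j] - x[j + 1])
    c(index = p, amplitude = h, prominence = prom, duration_s = (right - left) / fs)
  })
  out <- if (length(rows)) as.data.frame(do.call(rbind, rows)) else
    data.frame(index = numeric(0), amplitude = numeric(0), prominence = numeric(0), duration_s = numeric(0))
  out[out$duration_s >= min_width_s, , drop = FALSE]
}

# smooth random envelope for peak-detection cross-checks
random_envelope <- function(n = 3000, fs = 500) {
  t <- (seq_len(n) - 1) / fs
  k <- sample(2:6, 1)
  centers <- sort(stats::runif(k, 0.3, max(t) - 0.3))
  heights <- stats::runif(k, 0.05, 0.8)
  widths <- stats::runif(k, 0.03, 0.25)
  x <- rep(0.01, n)
  for (i in seq_len(k)) {
    x <- x + heights[i] * exp(-(t - centers[i])^2 / (2 * widths[i]^2))
  }
  x + 0.005 * sin(2 * pi * 0.7 * t)
}
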