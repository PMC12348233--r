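test_that("reduced distances match an independent Q/T2 recomputation", {
  X <- gauss_class(60, p = 12, seed = 2)
  m <- fit_simca(X, 3)
  d <- reduced_distance(m, X)
  # brute-force recomputation from first principles
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  P <- sv$v[, 1:3]
  eig <- sv$d^2 / (nrow(X) - 1)
  Tsc <- Xc %*% P
  Q <- rowSums((Xc - Tsc %*% t(P))^2)
  T2 <- rowSums(sweep(Tsc^2, 2, eig[1:3], "/"))
  d_oracle <- sqrt((Q / m$q_limit_95)^2 + (T2 / m$t2_limit_95)^2)
  expect_lt(max(abs(d - d_oracle)), 1e-12)
  # centroid sample: zero distance
  expect_equal(reduced_distance(m, matrix(mu, 1)), 0, tolerance = 1e-20)
})

test_that("a sample at both 95% limits has reduced distance sqrt(2)", {
  X <- gauss_class(80, p = 6, rank = 6, seed = 4)
  m <- fit_simca(X, 2)
  # in-subspace displacement giving T2 = t2_limit, plus an orthogonal
  # residual of squared norm q_limit
  u <- m$loadings[, 1] * sqrt(m$t2_limit_95 * m$eigenvalues[1])
  resid_dir <- qr.Q(qr(cbind(m$loadings, rnorm(6))))[, 3]
  x <- m$mean + u + resid_dir * sqrt(m$q_limit_95)
  expect_equal(reduced_distance(m, matrix(x, 1)), sqrt(2), tolerance = 1e-8)
})

test_that("data in an exact A-dimensional subspace give zero Q and a positive limit", {
  X <- gauss_class(40, p = 10, rank = 3, seed = 6)
  m <- fit_simca(X, 3)
  s <- predict(m, X)
  expect_lt(max(s$Q), 1e-18)
  expect_gt(m$q_limit_95, 0)
})

test_that("Q and T2 exceedance rates sit near 5% for Gaussian data", {
  # lighter version of the calibration study (the acceptance suite runs 20 seeds)
  rates <- vapply(1:5, function(s) {
    X <- gauss_class(500, p = 20, seed = 100 + s)
    m <- fit_simca(X, 3)
    st <- predict(m, X)
    c(mean(st$Q > m$q_limit_95), mean(st$T2 > m$t2_limit_95))
  }, numeric(2))
  expect_gt(mean(rates[1, ]), 0.03); expect_lt(mean(rates[1, ]), 0.07)
  expect_gt(mean(rates[2, ]), 0.03); expect_lt(mean(rates[2, ]), 0.07)
})

test_that("the acceptance region is monotone in both statistics", {
  X <- gauss_class(50, p = 8, seed = 12)
  m <- fit_simca(X, 2)
  st <- predict(m, X)
  for (a in 1:20) for (b in 1:20)
    if (st$Q[a] <= st$Q[b] && st$T2[a] <= st$T2[b] && st$accepted[b])
      expect_true(st$accepted[a])
})

test_that("threshold tuning matches an exhaustive scan and handles edge cases", {
  set.seed(31)
  for (case in 1:25) {
    dt <- rexp(15, 1); dn <- rexp(10, 0.4)
    thr <- optimize_threshold(dt, dn)
    obj <- function(t) 100 * mean(dt <= t) + 100 * mean(dn > t)
    grid <- seq(0, max(dt, dn) * 1.1, length.out = 4000)
    expect_gte(obj(thr) + 1e-9, max(vapply(grid, obj, 0)))
  }
  # perfect separation: both metrics 100%
  thr <- optimize_threshold(c(0.2, 0.5), c(1.2, 2))
  expect_equal(attr(thr, "sensitivity"), 100)
  expect_equal(attr(thr, "specificity"), 100)
  # fully degenerate sets: sensitivity + specificity is 100 at any threshold;
  # the tie-break goes to maximal sensitivity, then the smallest candidate
  thr2 <- optimize_threshold(c(1, 2), c(1, 2))
  expect_equal(attr(thr2, "sensitivity") + attr(thr2, "specificity"), 100)
  expect_equal(attr(thr2, "sensitivity"), 100)
})

test_that("LOO component selection matches a naive loop and finds a planted rank", {
  X <- gauss_class(25, p = 10, rank = 3, sd_decay = 1, seed = 3) +
    0.05 * matrix(rnorm(250), 25)
  sel <- select_n_components(X, 1:5)
  # naive-loop oracle: leave out the sample, then predict each variable from
  # the others via an explicit per-variable least-squares projection
  for (a_idx in 1:5) {
    press <- 0
    for (i in 1:25) {
      Xtr <- X[-i, ]
      mu <- colMeans(Xtr)
      P <- svd(sweep(Xtr, 2, mu))$v[, 1:a_idx, drop = FALSE]
      xi <- X[i, ] - mu
      for (j in 1:10) {
        t_loo <- solve(crossprod(P[-j, , drop = FALSE]),
                       crossprod(P[-j, , drop = FALSE], xi[-j]))
        press <- press + (xi[j] - P[j, , drop = FALSE] %*% t_loo)^2
      }
    }
    expect_lt(abs(sel$diagnostics$rmsecv[a_idx] - sqrt(press / 25 / 10)), 1e-10)
  }
  hits <- vapply(1:20, function(s) {
    Xs <- gauss_class(25, p = 10, rank = 3, sd_decay = 1, seed = 300 + s) +
      0.05 * matrix(rnorm(250), 25)
    select_n_components(Xs, 1:5)$chosen
  }, 0)
  expect_gte(sum(hits == 3), 16)
})

test_that("duplex split follows the hand-executed trace and is deterministic", {
  X <- matrix(0:9, ncol = 1)
  sp <- duplex_split(X, ratio = 0.8)
  # trace: round 1 (calibration) takes the farthest pair {0, 9}; round 2
  # (test) takes the farthest remaining pair {1, 8}; test is full at
  # ceiling(0.2 * 10) = 2, remainder to calibration
  expect_equal(sp$test, c(2, 9))
  expect_equal(sp$calibration, setdiff(1:10, c(2, 9)))
  expect_identical(sp, duplex_split(X, ratio = 0.8))
  expect_error(duplex_split(X[1:4, , drop = FALSE], 0.8), "at least 5")
})

test_that("replicates of one sample never straddle the duplex split", {
  set.seed(40)
  X <- matrix(rnorm(36 * 5), 36)
  groups <- rep(paste0("s", 1:12), each = 3)
  sp <- duplex_split(X, ratio = 0.8, groups = groups)
  expect_equal(length(sp$test) + length(sp$calibration), 36)
  for (g in unique(groups)) {
    rows <- which(groups == g)
    expect_true(all(rows %in% sp$test) || all(rows %in% sp$calibration))
  }
})

test_that("outlier screening flags spikes and spares clean data", {
  flags <- vapply(1:3, function(s) {
    X <- gauss_class(200, p = 10, seed = 50 + s)
    mean(screen_outliers(X, 3)$flagged)
  }, 0)
  expect_true(all(flags <= 0.10))
  for (s in 1:5) {
    X <- gauss_class(100, p = 10, seed = 60 + s)
    X[7, ] <- X[7, ] + 50 * apply(X, 2, sd)
    expect_true(screen_outliers(X, 3)$flagged[7])
  }
  # minimal n = A + 2 boundary runs
  expect_silent(screen_outliers(gauss_class(5, p = 6, seed = 1), 3))
})

test_that("classification metrics follow the confusion-count formulas", {
  m <- classification_metrics(TP = 3, FN = 0, TN = 1, FP = 1)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 50)
  expect_equal(m$accuracy, 80)
  all_right <- classification_metrics(4, 0, 3, 0)
  expect_equal(all_right$accuracy, 100)
  expect_true(is.na(classification_metrics(0, 0, 5, 1)$sensitivity))
})
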