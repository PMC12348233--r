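test_that("block normalization equalizes total variance and records divisors", {
  set.seed(2)
  blocks <- list(a = matrix(rnorm(50, sd = 1000), 10),
                 b = matrix(rnorm(80, sd = 1e-4), 10))
  nb <- normalize_blocks(blocks)
  for (b in nb) expect_equal(sum(b$matrix^2), 1, tolerance = 1e-12)
  # scale invariance
  nb10 <- normalize_blocks(list(a = 10 * blocks$a, b = blocks$b))
  expect_equal(nb10$a$matrix, nb$a$matrix, tolerance = 1e-12)
  expect_error(normalize_blocks(list(a = matrix(0, 10, 3), b = blocks$b)),
               "zero norm")
  rownames(blocks$a) <- paste0("r", 1:10); rownames(blocks$b) <- paste0("x", 1:10)
  expect_error(normalize_blocks(blocks), "do not match")
})

test_that("single-block ComDim reproduces PCA scores", {
  set.seed(7)
  X <- gauss_class(30, p = 15, seed = 7)
  cd <- fit_comdim(list(x = X), n_cd = 3)
  pca_scores <- svd(X)$u[, 1:3]
  for (h in 1:3)
    expect_gt(abs(cor(cd$global_scores[, h], pca_scores[, h])), 0.9999)
})

test_that("identical blocks share saliences and orthogonal blocks split them by energy", {
  X <- gauss_class(25, p = 12, seed = 9)
  cd <- fit_comdim(list(a = X, b = X), n_cd = 4)
  expect_lt(max(abs(cd$saliences["a", ] - cd$saliences["b", ])), 1e-9)
  # orthogonal row spaces, block a carries far more energy
  set.seed(11)
  base <- qr.Q(qr(matrix(rnorm(20 * 10), 20)))
  A <- matrix(rnorm(20 * 6), 20) %*% t(base[, 1:6]) * 10
  B <- matrix(rnorm(20 * 4), 20) %*% t(base[, 7:10]) * 0.1
  cd2 <- fit_comdim(list(a = A, b = B), n_cd = 1)
  share <- cd2$saliences["a", 1] / sum(cd2$saliences[, 1])
  expect_gt(share, 0.99)
})

test_that("explained variance exhausts the data and matches the salience bookkeeping", {
  # mean-centered blocks: 12 samples span 11 dimensions, so 11 CDs exhaust them
  X1 <- scale(gauss_class(12, p = 8, seed = 13), scale = FALSE)
  X2 <- scale(gauss_class(12, p = 5, seed = 14), scale = FALSE)
  nb <- normalize_blocks(list(a = X1, b = X2))
  cd <- fit_comdim(nb, n_cd = 11)
  ev <- explained_variance(cd)
  expect_gte(max(ev$cumulative), 99.99)
  expect_equal(ev$cumulative, cumsum(ev$percent), tolerance = 1e-9)
  # rank-3 concatenated data: 3 CDs suffice
  L <- matrix(rnorm(12 * 3), 12)
  low <- list(a = L %*% matrix(rnorm(3 * 7), 3), b = L %*% matrix(rnorm(3 * 6), 3))
  cd3 <- fit_comdim(normalize_blocks(low), n_cd = 3)
  expect_gte(sum(cd3$explained_variance), 99.99)
  # per-CD salience equals the variance of the block explained by that CD
  mats <- lapply(nb, `[[`, "matrix")
  for (h in 1:3) {
    q <- cd$global_scores[, h]
    for (b in 1:2) {
      expect_equal(cd$saliences[b, h], sum((crossprod(mats[[b]], q))^2),
                   tolerance = 1e-9)
      mats[[b]] <- mats[[b]] - q %*% crossprod(q, mats[[b]])
    }
  }
})

test_that("CD score vectors are mutually orthogonal", {
  X1 <- gauss_class(20, p = 10, seed = 15); X2 <- gauss_class(20, p = 7, seed = 16)
  cd <- fit_comdim(normalize_blocks(list(a = X1, b = X2)), n_cd = 5)
  G <- crossprod(cd$global_scores)
  expect_lt(max(abs(G - diag(5))), 1e-9)
})

test_that("projection replays training scores and maps duplicates identically", {
  X1 <- gauss_class(18, p = 9, seed = 17); X2 <- gauss_class(18, p = 6, seed = 18)
  nb <- normalize_blocks(list(a = X1, b = X2))
  cd <- fit_comdim(nb, n_cd = 3)
  proj <- project_comdim(cd, lapply(nb, `[[`, "matrix"))
  expect_lt(max(abs(proj$scores - cd$global_scores)), 1e-9)
  # a new sample equal to training row 4 gets row 4's scores
  new_blocks <- lapply(nb, function(b) b$matrix[4, , drop = FALSE])
  proj1 <- project_comdim(cd, new_blocks)
  expect_equal(as.numeric(proj1$scores), as.numeric(cd$global_scores[4, ]),
               tolerance = 1e-9)
  expect_error(project_comdim(cd, list(X1[, 1:3], X2)), "variables")
})

test_that("projected held-out samples land nearest their own class centroid", {
  hits <- vapply(1:20, function(s) {
    set.seed(700 + s)
    centers <- matrix(rnorm(3 * 6, sd = 3), 3)
    lab <- rep(1:3, each = 8)
    X <- centers[lab, ] + matrix(rnorm(24 * 6), 24)
    blocks <- list(a = X[, 1:3], b = X[, 4:6])
    tr <- seq_len(18); te <- 19:24
    nb <- normalize_blocks(lapply(blocks, function(B) B[tr, , drop = FALSE]))
    cd <- fit_comdim(nb, n_cd = 2)
    newn <- lapply(seq_along(blocks), function(b)
      blocks[[b]][te, , drop = FALSE] /
        (nb[[b]]$divisor_point * nb[[b]]$divisor_frob))
    sc_te <- project_comdim(cd, newn)$scores
    cent <- vapply(1:3, function(g)
      colMeans(cd$global_scores[lab[tr] == g, , drop = FALSE]), numeric(2))
    pred <- apply(sc_te, 1, function(x) which.min(colSums((cent - x)^2)))
    mean(pred == lab[te])
  }, 0)
  expect_gte(mean(hits >= 0.9), 0.9)
})

test_that("the multiblock one-class model obeys its closed-form distance rule", {
  X1 <- gauss_class(30, p = 10, seed = 19); X2 <- gauss_class(30, p = 8, seed = 20)
  occ <- fit_mb_occ(list(a = X1, b = X2), n_cd = 3)
  pr <- predict(occ, list(a = X1, b = X2))
  # independent recomputation of the reduced distance
  d_oracle <- sqrt((pr$SD / occ$sd_limit_95)^2 + (pr$OD / occ$od_limit_95)^2)
  expect_lt(max(abs(pr$distance - d_oracle)), 1e-12)
  # the centroid of the target class projects to SD = 0
  cent <- list(a = matrix(colMeans(X1), 1), b = matrix(colMeans(X2), 1))
  expect_lt(predict(occ, cent)$SD, 1e-8)
  expect_error(fit_mb_occ(list(a = X1[1:3, ], b = X2[1:3, ]), n_cd = 3), "below")
})

test_that("single-block mb-occ decisions agree with SIMCA on the same data", {
  set.seed(23)
  agree <- vapply(1:5, function(s) {
    Xt <- gauss_class(40, p = 10, rank = 6, seed = 23 + s)
    Xn <- gauss_class(20, p = 10, rank = 6, seed = 230 + s) + 1.5
    occ <- fit_mb_occ(list(x = Xt), n_cd = 3)
    sm <- fit_simca(Xt, 3)
    a1 <- predict(occ, list(x = rbind(Xt, Xn)))$accepted
    a2 <- predict(sm, rbind(Xt, Xn))$accepted
    mean(a1 == a2)
  }, 0)
  expect_gte(mean(agree), 0.95)
})
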