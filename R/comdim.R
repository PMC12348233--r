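#' Normalize data blocks to equal total variance
#'
#' Two-stage block normalization for multiblock analysis: each block is
#' first divided by the square root of its sum of squared values, then (on
#' concatenation) by its Frobenius norm, so every block ends with Frobenius
#' norm 1 and the same total variance. Both divisors are recorded so the
#' identical scaling can be replayed on new samples.
#'
#' @param blocks Named list of numeric matrices sharing the same ordered
#'   sample set (rownames are checked when present).
#' @return A list of `block` objects (`matrix`, `block_name`,
#'   `divisor_point`, `divisor_frob`).
#' @export
normalize_blocks <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    names(blocks) <- paste0("block", seq_along(blocks))
  rn <- lapply(blocks, rownames)
  n <- vapply(blocks, nrow, 1L)
  if (length(unique(n)) != 1)
    fail("blocks have different sample counts: %s", paste(n, collapse = ", "))
  if (!is.null(rn[[1]]))
    for (b in seq_along(blocks))
      if (!identical(rn[[b]], rn[[1]]))
        fail("sample sets of the blocks do not match exactly (block '%s')",
             names(blocks)[b])
  out <- lapply(seq_along(blocks), function(b) {
    X <- as.matrix(blocks[[b]])
    d1 <- sqrt(sum(X^2))
    if (!(d1 > 0)) fail("block '%s' has zero norm", names(blocks)[b])
    X <- X / d1
    d2 <- sqrt(sum(X^2))   # 1 after the first stage; recorded for replay
    structure(list(matrix = X / d2, block_name = names(blocks)[b],
                   divisor_point = d1, divisor_frob = d2), class = "block")
  })
  names(out) <- names(blocks)
  out
}

# replay recorded divisors on new samples of the same blocks
apply_block_normalization <- function(new_blocks, trained) {
  stopifnot(length(new_blocks) == length(trained))
  lapply(seq_along(trained), function(b) {
    X <- as.matrix(new_blocks[[b]])
    if (ncol(X) != ncol(trained[[b]]$matrix))
      fail("block '%s': %d variables, trained on %d",
           trained[[b]]$block_name, ncol(X), ncol(trained[[b]]$matrix))
    X / (trained[[b]]$divisor_point * trained[[b]]$divisor_frob)
  })
}

#' Fit a ComDim (CCSWA) multiblock model
#'
#' Extracts successive common dimensions (CDs). For each CD the algorithm
#' iterates: form the salience-weighted sum of the blocks' sample
#' association matrices `W = sum_b lambda_b X_b X_b'`, take its leading unit
#' eigenvector `q` as the CD score, and update each block's salience
#' `lambda_b = q' X_b X_b' q` (the variance of block b along the CD), until
#' the saliences stabilize. Each block is then deflated by the CD
#' (`X_b <- X_b - q q' X_b`) and the process repeats. Eigenvector signs are
#' fixed by making the largest-magnitude score positive.
#'
#' @param blocks Output of [normalize_blocks()] (or a named list of
#'   matrices, used as given).
#' @param n_cd Number of common dimensions.
#' @param tol Convergence tolerance on the salience change (default 1e-10).
#' @param max_iter Maximum salience iterations per CD (default 500).
#' @return An object of class `comdim_model`: `global_scores` (unit-norm
#'   columns), `saliences` (blocks x CDs), `block_loadings` (per block),
#'   `explained_variance` per CD (%), projection constants and a
#'   convergence log.
#' @export
fit_comdim <- function(blocks, n_cd = 3, tol = 1e-10, max_iter = 500) {
  if (inherits(blocks, "block")) blocks <- list(blocks)
  mats <- lapply(blocks, function(b) if (inherits(b, "block")) b$matrix else as.matrix(b))
  bnames <- if (!is.null(names(blocks))) names(blocks) else paste0("block", seq_along(blocks))
  nb <- length(mats)
  n <- nrow(mats[[1]])
  for (b in seq_len(nb))
    if (nrow(mats[[b]]) != n) fail("blocks have different sample counts")
  if (n_cd >= n) fail("n_cd must be smaller than the number of samples (%d)", n)
  rn <- rownames(mats[[1]])

  total_ss <- sum(vapply(mats, function(X) sum(X^2), numeric(1)))
  scores <- matrix(NA_real_, n, n_cd, dimnames = list(rn, paste0("CD", seq_len(n_cd))))
  sal <- matrix(NA_real_, nb, n_cd, dimnames = list(bnames, paste0("CD", seq_len(n_cd))))
  lambda_proj <- sal
  mu <- numeric(n_cd)
  loadings <- lapply(mats, function(X)
    matrix(NA_real_, ncol(X), n_cd, dimnames = list(colnames(X), paste0("CD", seq_len(n_cd)))))
  names(loadings) <- bnames
  iters <- integer(n_cd); conv <- logical(n_cd)

  X <- mats
  for (h in seq_len(n_cd)) {
    lambda <- rep(1, nb)
    it <- 0; converged <- FALSE
    XX <- lapply(X, tcrossprod)
    q <- NULL
    repeat {
      it <- it + 1
      W <- matrix(0, n, n)
      for (b in seq_len(nb)) W <- W + lambda[b] * XX[[b]]
      eg <- eigen(W, symmetric = TRUE)
      q <- eg$vectors[, 1]
      if (q[which.max(abs(q))] < 0) q <- -q
      lambda_new <- vapply(seq_len(nb), function(b) sum((crossprod(X[[b]], q))^2),
                           numeric(1))
      if (max(abs(lambda_new - lambda)) < tol) {
        converged <- TRUE
        # final eigen pass with the converged saliences keeps projection exact
        W <- matrix(0, n, n)
        for (b in seq_len(nb)) W <- W + lambda_new[b] * XX[[b]]
        eg <- eigen(W, symmetric = TRUE)
        q <- eg$vectors[, 1]
        if (q[which.max(abs(q))] < 0) q <- -q
        lambda <- lambda_new
        break
      }
      lambda <- lambda_new
      if (it >= max_iter) break
    }
    mu[h] <- eg$values[1]
    lambda_proj[, h] <- lambda
    scores[, h] <- q
    for (b in seq_len(nb)) {
      w <- as.vector(crossprod(X[[b]], q))
      loadings[[b]][, h] <- w
      sal[b, h] <- sum(w^2)
      X[[b]] <- X[[b]] - q %*% crossprod(q, X[[b]])
    }
    iters[h] <- it; conv[h] <- converged
  }
  structure(list(
    global_scores = scores, saliences = sal, block_loadings = loadings,
    lambda_proj = lambda_proj, mu = mu,
    explained_variance = 100 * colSums(sal) / total_ss,
    total_ss = total_ss, n_cd = n_cd, block_names = bnames,
    n_variables = vapply(mats, ncol, 1L),
    blocks = if (all(vapply(blocks, inherits, TRUE, "block"))) blocks else NULL,
    convergence = list(iterations = iters, converged = conv)
  ), class = "comdim_model")
}

#' @export
print.comdim_model <- function(x, ...) {
  cat(sprintf("comdim_model: %d blocks (%s), %d CDs, cumulative variance %.1f%%\n",
              length(x$block_names), paste(x$block_names, collapse = ", "),
              x$n_cd, sum(x$explained_variance)))
  invisible(x)
}

#' Explained variance of a ComDim model
#'
#' Percentage of the total variance of the concatenated normalized blocks
#' captured by each common dimension (the deflated sum of squares), and the
#' cumulative values.
#'
#' @param model A `comdim_model`.
#' @return Data frame with `cd`, `percent`, `cumulative`.
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "comdim_model"))
  data.frame(cd = seq_len(model$n_cd),
             percent = as.numeric(model$explained_variance),
             cumulative = cumsum(as.numeric(model$explained_variance)))
}

#' Project new samples onto a fitted ComDim model
#'
#' Replays the training deflation sequence: for each CD, the new sample's
#' score is the salience-weighted combination of its block images on the
#' stored loadings (scaled by the CD eigenvalue), after which the sample is
#' deflated exactly as the training blocks were. Training samples projected
#' through this path reproduce their fitted scores.
#'
#' @param model A `comdim_model`.
#' @param new_blocks List of matrices on the training variable sets, already
#'   normalized with the training divisors (see [normalize_blocks()] /
#'   `apply_block_normalization`).
#' @return A list with `scores` (samples x CDs) and `residuals` (list of
#'   deflated block remainders after all CDs).
#' @export
project_comdim <- function(model, new_blocks) {
  stopifnot(inherits(model, "comdim_model"))
  mats <- lapply(new_blocks, function(b) if (inherits(b, "block")) b$matrix else as.matrix(b))
  if (length(mats) != length(model$block_names))
    fail("expected %d blocks, got %d", length(model$block_names), length(mats))
  for (b in seq_along(mats))
    if (ncol(mats[[b]]) != model$n_variables[b])
      fail("block '%s' has %d variables; model was fitted on %d",
           model$block_names[b], ncol(mats[[b]]), model$n_variables[b])
  m <- nrow(mats[[1]])
  scores <- matrix(NA_real_, m, model$n_cd,
                   dimnames = list(rownames(mats[[1]]), paste0("CD", seq_len(model$n_cd))))
  for (h in seq_len(model$n_cd)) {
    t_h <- numeric(m)
    for (b in seq_along(mats))
      t_h <- t_h + model$lambda_proj[b, h] *
        as.vector(mats[[b]] %*% model$block_loadings[[b]][, h])
    t_h <- t_h / model$mu[h]
    scores[, h] <- t_h
    for (b in seq_along(mats))
      mats[[b]] <- mats[[b]] - t_h %*% t(model$block_loadings[[b]][, h])
  }
  list(scores = scores, residuals = mats)
}

# per-block residual sums of squares as a samples x blocks matrix
od_by_block <- function(residuals) {
  m <- nrow(residuals[[1]])
  out <- vapply(residuals, function(R) rowSums(R^2), numeric(m))
  if (m == 1) out <- matrix(out, nrow = 1)
  out
}

# moment-matched scaled chi-square 95% limit for a positive statistic
chi2_limit <- function(x, alpha = 0.05) {
  m <- mean(x); v <- stats::var(x)
  if (!is.finite(v) || v <= 0 || m <= 0) return(max(x) + .Machine$double.eps)
  g <- v / (2 * m); h <- 2 * m^2 / v
  g * stats::qchisq(1 - alpha, h)
}

#' Multiblock one-class classifier on ComDim scores (SD/OD)
#'
#' Fits a ComDim model on target-class samples only and bounds it by two
#' statistics: the score distance SD (Mahalanobis distance of a sample's
#' CD-score vector to the target score cloud, used without further
#' pre-processing) and the orthogonal distance OD (residual sum of squares
#' of the concatenated blocks after reconstruction from the CDs). 95%
#' limits are estimated from the training distributions by moment-matched
#' scaled chi-square (on SD^2 and OD), or empirical quantiles. The reduced
#' distance is `d = sqrt((SD/sd_limit)^2 + (OD/od_limit)^2)`; acceptance at
#' `d <= threshold` (sqrt(2) default; tune with [optimize_threshold()]).
#'
#' @param blocks_target Named list of raw target-class matrices (same
#'   ordered samples); block normalization is fitted here and replayed at
#'   prediction time.
#' @param n_cd Number of common dimensions (must be < target sample count).
#' @param limit_method `"chi2"` (default) or `"quantile"`.
#' @param od_mode `"concatenated"` (default) or `"blockwise"` (per-block ODs
#'   normalized by per-block limits, then averaged).
#' @param alpha Significance level (default 0.05).
#' @param center Mean-center each block against the target-class column
#'   means before normalization (default TRUE); the means are stored and
#'   replayed on new samples.
#' @param target_label Class label for reports.
#' @return An object of class `mb_occ`.
#' @export
fit_mb_occ <- function(blocks_target, n_cd = 3,
                       limit_method = c("chi2", "quantile"),
                       od_mode = c("concatenated", "blockwise"),
                       alpha = 0.05, center = TRUE, target_label = "target") {
  limit_method <- match.arg(limit_method)
  od_mode <- match.arg(od_mode)
  n <- nrow(as.matrix(blocks_target[[1]]))
  if (n_cd >= n) fail("n_cd = %d must be below the target sample count %d", n_cd, n)
  block_means <- lapply(blocks_target, function(X) {
    if (center) colMeans(as.matrix(X)) else rep(0, ncol(as.matrix(X)))
  })
  blocks_target <- lapply(seq_along(blocks_target), function(b)
    sweep(as.matrix(blocks_target[[b]]), 2, block_means[[b]]))
  names(blocks_target) <- names(block_means)
  nb <- normalize_blocks(blocks_target)
  cd <- fit_comdim(nb, n_cd = n_cd)

  S <- cd$global_scores
  mu_s <- colMeans(S)
  cov_s <- stats::cov(S)
  if (rcond(cov_s) < 1e-14) fail("score covariance is singular; reduce n_cd")
  cov_inv <- solve(cov_s)
  sd2 <- stats::mahalanobis(S, mu_s, cov_s)
  proj <- project_comdim(cd, lapply(nb, `[[`, "matrix"))
  od_block <- od_by_block(proj$residuals)
  od <- rowSums(od_block)

  lim <- function(x) if (limit_method == "chi2") chi2_limit(x, alpha)
                     else as.numeric(stats::quantile(x, 1 - alpha, type = 7))
  sd_limit <- sqrt(lim(sd2))
  od_limit <- if (od_mode == "concatenated") lim(od) else apply(od_block, 2, lim)

  structure(list(comdim = cd, trained_blocks = nb, block_means = block_means,
                 score_mean = mu_s, score_cov = cov_s, score_cov_inv = cov_inv,
                 sd_limit_95 = sd_limit, od_limit_95 = od_limit,
                 od_mode = od_mode, limit_method = limit_method,
                 threshold = sqrt(2), alpha = alpha,
                 target_label = target_label), class = "mb_occ")
}

#' @export
print.mb_occ <- function(x, ...) {
  cat(sprintf("mb_occ '%s': %d CDs on %d blocks, SD95 = %.4g, OD95 = %s, threshold = %.4g\n",
              x$target_label, x$comdim$n_cd, length(x$comdim$block_names),
              x$sd_limit_95, paste(signif(x$od_limit_95, 4), collapse = "/"),
              x$threshold))
  invisible(x)
}

#' Score distance, orthogonal distance and acceptance for new samples
#'
#' @param object An `mb_occ` model.
#' @param newdata Named list of raw block matrices (training variable sets);
#'   the training normalization is replayed before projection.
#' @param ... Unused.
#' @return Data frame with `SD`, `OD`, `distance`, `accepted`.
#' @export
predict.mb_occ <- function(object, newdata, ...) {
  newdata <- lapply(seq_along(newdata), function(b)
    sweep(as.matrix(newdata[[b]]), 2, object$block_means[[b]]))
  mats <- apply_block_normalization(newdata, object$trained_blocks)
  proj <- project_comdim(object$comdim, mats)
  sd2 <- stats::mahalanobis(proj$scores, object$score_mean, object$score_cov_inv,
                            inverted = TRUE)
  SD <- sqrt(pmax(sd2, 0))
  od_block <- od_by_block(proj$residuals)
  if (object$od_mode == "concatenated") {
    odn <- rowSums(od_block) / object$od_limit_95
    OD <- rowSums(od_block)
  } else {
    odn <- rowMeans(sweep(od_block, 2, object$od_limit_95, "/"))
    OD <- rowSums(od_block)
  }
  d <- sqrt((SD / object$sd_limit_95)^2 + odn^2)
  data.frame(SD = SD, OD = OD, distance = d, accepted = d <= object$threshold)
}
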