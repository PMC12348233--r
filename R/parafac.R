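# column-wise Khatri-Rao product with the V index running fastest,
# matching the mode-n matricizations used by the ALS updates
khatri_rao <- function(U, V) {
  out <- matrix(0, nrow(U) * nrow(V), ncol(U))
  for (f in seq_len(ncol(U))) out[, f] <- as.vector(V[, f] %o% U[, f])
  out
}

#' Fast non-negative least squares on the normal equations
#'
#' Active-set solver for `min ||Z x - y||` s.t. `x >= 0`, given `Z'Z` and
#' `Z'y` (Bro-de Jong FNNLS). Used row-wise inside the non-negative ALS
#' updates, where `Z'Z` is a small F x F matrix shared by all rows.
#'
#' @param ZtZ Cross-product matrix `Z'Z` (F x F).
#' @param Zty Right-hand side `Z'y` (length F).
#' @return Non-negative solution vector of length F.
#' @export
fnnls <- function(ZtZ, Zty, tol = NULL) {
  n <- length(Zty)
  if (is.null(tol)) tol <- .Machine$double.eps * max(abs(ZtZ)) * n * 10
  p <- logical(n)
  x <- numeric(n)
  w <- Zty - as.vector(ZtZ %*% x)
  solve_p <- function(p) {
    s <- numeric(n)
    s[p] <- tryCatch(solve(ZtZ[p, p, drop = FALSE], Zty[p]),
                     error = function(e)
                       solve(ZtZ[p, p, drop = FALSE] +
                               diag(1e-10 * (max(abs(ZtZ)) + 1), sum(p)), Zty[p]))
    s
  }
  outer_it <- 0
  while (any(!p) && any(w[!p] > tol) && outer_it < 30 * n) {
    outer_it <- outer_it + 1
    cand <- which(!p)
    p[cand[which.max(w[cand])]] <- TRUE
    s <- solve_p(p)
    inner_it <- 0
    while (any(s[p] <= tol) && inner_it < 30 * n) {
      inner_it <- inner_it + 1
      q <- p & s <= tol
      alpha <- min(x[q] / (x[q] - s[q]))
      x <- x + alpha * (s - x)
      p[p & x <= tol] <- FALSE
      s <- solve_p(p)
    }
    x <- s
    w <- Zty - as.vector(ZtZ %*% x)
  }
  pmax(x, 0)
}

# batched exact NNLS for all rows sharing one small Gram matrix G: since the
# optimum's support is one of the 2^F - 1 non-empty subsets, solve each
# candidate support for all rows at once and keep the KKT-valid one
nnls_enumerate <- function(G, M, tol) {
  Fc <- ncol(G)
  n <- nrow(M)
  X <- matrix(0, n, Fc)
  unsolved <- rep(TRUE, n)
  safe_solve <- function(Gs)
    tryCatch(solve(Gs), error = function(e)
      tryCatch(solve(Gs + diag(1e-10 * (max(abs(Gs)) + 1), nrow(Gs))),
               error = function(e2) NULL))
  supports <- order(vapply(seq_len(2^Fc - 1), function(s) -sum(bitwAnd(s, 2^(0:(Fc - 1))) > 0), 0))
  for (s in supports) {
    if (!any(unsolved)) break
    idx <- which(bitwAnd(s, 2^(0:(Fc - 1))) > 0)
    Gi <- safe_solve(G[idx, idx, drop = FALSE])
    if (is.null(Gi)) next
    Xi <- M[unsolved, idx, drop = FALSE] %*% Gi
    feasible <- rowSums(Xi < -tol) == 0
    if (!any(feasible)) next
    comp <- setdiff(seq_len(Fc), idx)
    ok <- feasible
    if (length(comp)) {
      W <- M[unsolved, comp, drop = FALSE] - Xi %*% G[idx, comp, drop = FALSE]
      ok <- feasible & rowSums(W > tol) == 0
    }
    if (any(ok)) {
      rows <- which(unsolved)[ok]
      Xfull <- matrix(0, length(rows), Fc)
      Xfull[, idx] <- pmax(Xi[ok, , drop = FALSE], 0)
      X[rows, ] <- Xfull
      unsolved[rows] <- FALSE
    }
  }
  for (i in which(unsolved)) X[i, ] <- fnnls(G, M[i, ])
  X
}

# solve the mode update M = X(n) %*% KR; unconstrained first, exact NNLS only
# for rows that violate non-negativity (the solutions coincide when the
# unconstrained optimum is feasible)
mode_update <- function(M, G, nonneg = TRUE) {
  Gi <- tryCatch(solve(G), error = function(e)
    solve(G + diag(1e-10 * (max(abs(G)) + 1), nrow(G))))
  A <- M %*% Gi
  if (nonneg && any(A < 0)) {
    tol <- .Machine$double.eps * max(abs(G)) * ncol(G) * 100
    bad <- rowSums(A < -tol) > 0
    if (any(bad)) {
      if (ncol(G) <= 8)
        A[bad, ] <- nnls_enumerate(G, M[bad, , drop = FALSE], tol)
      else
        for (i in which(bad)) A[i, ] <- fnnls(G, M[i, ])
    }
    A[A < 0] <- 0
  }
  A
}

#' Fit a non-negative PARAFAC (trilinear) model to an EEM cube
#'
#' Alternating least squares with non-negativity enforced on all three modes
#' (sample scores, emission loadings, excitation loadings). Runs from
#' several initializations (one SVD-based, the rest random, all seeded) and
#' keeps the best fit; convergence is declared when the relative change of
#' the residual sum of squares falls below `tol`. Emission and excitation
#' loading columns are scaled to unit maximum, with the scale carried in the
#' scores; components are ordered by explained magnitude.
#'
#' @param cube An [eem_cube()] without missing values, or a 3-way array
#'   (samples x emission x excitation).
#' @param n_components Number of trilinear components F (>= 1).
#' @param n_starts Number of initializations (default 10: 1 SVD + 9 random).
#' @param tol Relative fit-change convergence tolerance (default 1e-8).
#' @param max_iter Maximum ALS iterations per start (default 2000).
#' @param seed RNG seed for the random starts.
#' @param nonneg Enforce non-negativity (default TRUE).
#' @return An object of class `parafac_model`: `scores`, `em_loadings`,
#'   `ex_loadings`, `F`, `explained_variance` (%), `corcondia` (%),
#'   `convergence` (per-start summary and the best start's loss trace).
#' @export
fit_parafac <- function(cube, n_components, n_starts = 10, tol = 1e-8,
                        max_iter = 2000, seed = 1, nonneg = TRUE) {
  X <- if (inherits(cube, "eem_cube")) cube$data else cube
  stopifnot(length(dim(X)) == 3, n_components >= 1)
  if (anyNA(X)) fail("cube contains missing values; interpolate first")
  dd <- dim(X)
  I <- dd[1]; J <- dd[2]; K <- dd[3]
  Fc <- as.integer(n_components)
  X1 <- matrix(X, I, J * K)                      # columns: em fastest
  X2 <- matrix(aperm(X, c(2, 1, 3)), J, I * K)   # columns: sample fastest
  X3 <- matrix(aperm(X, c(3, 1, 2)), K, I * J)
  ssX <- sum(X^2)

  init_factors <- function(start) {
    if (start == 1) {
      a <- abs(svd(X1, nu = min(Fc, I))$u)
      b <- abs(svd(X2, nu = min(Fc, J))$u)
      cc <- abs(svd(X3, nu = min(Fc, K))$u)
      pad <- function(M, n) {
        if (ncol(M) < Fc) M <- cbind(M, matrix(stats::runif(n * (Fc - ncol(M))), n))
        M[, seq_len(Fc), drop = FALSE]
      }
      list(A = pad(a, I), B = pad(b, J), C = pad(cc, K))
    } else {
      list(A = matrix(stats::runif(I * Fc), I),
           B = matrix(stats::runif(J * Fc), J),
           C = matrix(stats::runif(K * Fc), K))
    }
  }

  run_als <- function(fac) {
    A <- fac$A; B <- fac$B; C <- fac$C
    trace <- numeric(0)
    ssr_prev <- Inf
    converged <- FALSE
    it <- 0
    while (it < max_iter) {
      it <- it + 1
      G <- crossprod(C) * crossprod(B)
      M <- X1 %*% khatri_rao(C, B)
      A <- mode_update(M, G, nonneg)
      B <- mode_update(X2 %*% khatri_rao(C, A), crossprod(C) * crossprod(A), nonneg)
      C <- mode_update(X3 %*% khatri_rao(B, A), crossprod(B) * crossprod(A), nonneg)
      # rescale B, C columns to unit norm, push scale into A (guards drift)
      for (M2 in c("B", "C")) {
        Mm <- get(M2)
        nrm <- sqrt(colSums(Mm^2)); nrm[nrm == 0] <- 1
        assign(M2, sweep(Mm, 2, nrm, "/"))
        A <- sweep(A, 2, nrm, "*")
      }
      G <- crossprod(C) * crossprod(B)
      M <- X1 %*% khatri_rao(C, B)
      ssr <- ssX - 2 * sum(A * M) + sum(crossprod(A) * G)
      trace <- c(trace, ssr)
      if (is.finite(ssr_prev) && abs(ssr_prev - ssr) <= tol * max(ssr_prev, 1e-300)) {
        converged <- TRUE
        break
      }
      ssr_prev <- ssr
    }
    list(A = A, B = B, C = C, ssr = max(trace[length(trace)], 0),
         iterations = it, converged = converged, trace = trace)
  }

  set.seed(as.integer(seed) %% 2147483647L)
  best <- NULL
  start_log <- data.frame(start = integer(0), ssr = numeric(0),
                          iterations = integer(0), converged = logical(0))
  for (s in seq_len(n_starts)) {
    res <- run_als(init_factors(s))
    start_log <- rbind(start_log,
                       data.frame(start = s, ssr = res$ssr,
                                  iterations = res$iterations,
                                  converged = res$converged))
    if (is.null(best) || res$ssr < best$ssr) best <- res
  }

  # unit-maximum scaling of loading columns, scale carried in the scores
  A <- best$A; B <- best$B; C <- best$C
  for (f in seq_len(Fc)) {
    mb <- max(B[, f]); mc <- max(C[, f])
    if (mb > 0) { B[, f] <- B[, f] / mb; A[, f] <- A[, f] * mb }
    if (mc > 0) { C[, f] <- C[, f] / mc; A[, f] <- A[, f] * mc }
  }
  ord <- order(colSums(A^2), decreasing = TRUE)
  A <- A[, ord, drop = FALSE]; B <- B[, ord, drop = FALSE]; C <- C[, ord, drop = FALSE]
  colnames(A) <- colnames(B) <- colnames(C) <- paste0("C", seq_len(Fc))
  if (inherits(cube, "eem_cube")) {
    rownames(A) <- cube$sample_ids
    rownames(B) <- as.character(cube$em_axis)
    rownames(C) <- as.character(cube$ex_axis)
  }
  model <- structure(list(
    scores = A, em_loadings = B, ex_loadings = C, F = Fc,
    explained_variance = 100 * (1 - best$ssr / ssX),
    corcondia = NA_real_,
    convergence = list(starts = start_log, best_trace = best$trace,
                       iterations = best$iterations, converged = best$converged)
  ), class = "parafac_model")
  # degenerate over-factored fits can make the core fit singular; the model
  # is still returned, with the diagnostic marked unavailable
  model$corcondia <- tryCatch(corcondia(model, X), error = function(e) NA_real_)
  model
}

#' @export
print.parafac_model <- function(x, ...) {
  cat(sprintf("parafac_model: F = %d, explained variance = %.2f%%, CORCONDIA = %.1f%%%s\n",
              x$F, x$explained_variance, x$corcondia,
              if (!x$convergence$converged) " (NOT converged)" else ""))
  invisible(x)
}

#' Core consistency diagnostic (CORCONDIA)
#'
#' Computes `100 * (1 - sum((g - t)^2) / sum(t^2))` where `g` is the
#' least-squares Tucker core given the fitted PARAFAC factors and `t` is the
#' superidentity core. Near 100 when the trilinear model is appropriate;
#' collapses when the model is over-factored. For a one-component model the
#' diagnostic is 100 by definition.
#'
#' @param model A `parafac_model`.
#' @param cube The cube (or array) the model was fitted on.
#' @return CORCONDIA percentage (can be negative).
#' @export
corcondia <- function(model, cube) {
  stopifnot(inherits(model, "parafac_model"))
  X <- if (inherits(cube, "eem_cube")) cube$data else cube
  Fc <- model$F
  if (Fc == 1) return(100)
  pinv <- function(M) {
    G <- crossprod(M)
    if (rcond(G) < 1e-12)
      fail("factor covariance is numerically singular; try fewer components")
    solve(G, t(M))
  }
  Pa <- pinv(model$scores); Pb <- pinv(model$em_loadings); Pc <- pinv(model$ex_loadings)
  dd <- dim(X)
  # successive mode products: core = X x1 Pa x2 Pb x3 Pc (F x F x F)
  Y <- Pa %*% matrix(X, dd[1], dd[2] * dd[3])            # F x (J*K)
  Y <- array(Y, c(Fc, dd[2], dd[3]))
  Y2 <- Pb %*% matrix(aperm(Y, c(2, 1, 3)), dd[2], Fc * dd[3])
  Y2 <- array(Y2, c(Fc, Fc, dd[3]))                      # em-mode compressed
  Y2 <- aperm(Y2, c(2, 1, 3))                            # back to (F, F, K)
  Y3 <- Pc %*% matrix(aperm(Y2, c(3, 1, 2)), dd[3], Fc * Fc)
  core <- aperm(array(Y3, c(Fc, Fc, Fc)), c(2, 3, 1))
  super <- array(0, c(Fc, Fc, Fc))
  for (f in seq_len(Fc)) super[f, f, f] <- 1
  100 * (1 - sum((core - super)^2) / Fc)
}

#' Scan component numbers and choose the trilinear rank
#'
#' Fits PARAFAC for each F in `F_range` and tabulates CORCONDIA, explained
#' variance and iteration counts. The chosen F is the largest with
#' CORCONDIA at or above `threshold` (default 80) — a documented, automatic
#' stand-in for visual inspection of the diagnostics. If the chosen model
#' explains little variance the result is flagged.
#'
#' @param cube An [eem_cube()] or array without missing values.
#' @param F_range Integer vector of candidate component numbers.
#' @param threshold CORCONDIA acceptance level (default 80).
#' @param ... Passed to [fit_parafac()].
#' @return A list with `chosen` (F), `diagnostics` (data frame per F),
#'   `low_variance` flag, and `models` (fitted models, named by F).
#' @export
select_components <- function(cube, F_range = 1:5, threshold = 80, ...) {
  stopifnot(length(F_range) >= 1)
  F_range <- sort(unique(as.integer(F_range)))
  models <- list()
  diag_df <- data.frame(F = F_range, corcondia = NA_real_,
                        explained_variance = NA_real_, iterations = NA_integer_,
                        converged = NA)
  for (i in seq_along(F_range)) {
    m <- fit_parafac(cube, F_range[i], ...)
    models[[as.character(F_range[i])]] <- m
    diag_df$corcondia[i] <- m$corcondia
    diag_df$explained_variance[i] <- m$explained_variance
    diag_df$iterations[i] <- m$convergence$iterations
    diag_df$converged[i] <- m$convergence$converged
  }
  ok <- diag_df$F[!is.na(diag_df$corcondia) & diag_df$corcondia >= threshold]
  chosen <- if (length(ok)) max(ok) else min(F_range)
  ev <- diag_df$explained_variance[diag_df$F == chosen]
  list(chosen = chosen, diagnostics = diag_df,
       low_variance = is.finite(ev) && ev < 50,
       models = models)
}
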