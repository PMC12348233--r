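# Jackson-Mudholkar closed-form 95% limit for the Q residual, from the
# eigenvalues discarded by the PCA model; degenerate residual spectra
# (exact low-rank data) give a vanishing positive limit
q_limit_jm <- function(resid_eigs, alpha = 0.05) {
  th1 <- sum(resid_eigs)
  th2 <- sum(resid_eigs^2)
  th3 <- sum(resid_eigs^3)
  if (th1 <= 0 || th2 <= 0) return(.Machine$double.eps)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (!is.finite(h0) || h0 < 1e-3) h0 <- 1e-3
  z <- stats::qnorm(1 - alpha)
  th1 * (z * sqrt(2 * th2 * h0^2) / th1 + 1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
}

#' Fit a one-class SIMCA model
#'
#' Builds a PCA model of the target class (mean-centered internally against
#' the target-class means) and bounds it by two 95% confidence limits: the
#' Jackson-Mudholkar closed form for the Q residual (distance from the PCA
#' subspace) and the F-distribution form for Hotelling's T2 (leverage
#' within the subspace). A sample is accepted when its reduced distance
#' (both statistics normalized over their limits, combined in Euclidean
#' form) does not exceed the model threshold — sqrt(2) by default, normally
#' re-tuned with [optimize_threshold()].
#'
#' @param X_target Numeric matrix, target-class training samples x variables.
#' @param n_components Number of retained principal components A.
#' @param alpha Significance level of the limits (default 0.05).
#' @param target_label Class label carried in reports.
#' @param distance_form `"euclidean"` (default) or `"sum"` combination of the
#'   two normalized statistics.
#' @return An object of class `simca_model`.
#' @export
fit_simca <- function(X_target, n_components, alpha = 0.05,
                      target_label = "target",
                      distance_form = c("euclidean", "sum")) {
  stopifnot(is.matrix(X_target))
  distance_form <- match.arg(distance_form)
  n <- nrow(X_target); p <- ncol(X_target)
  A <- as.integer(n_components)
  if (n < A + 2) fail("need at least A + 2 = %d rows, got %d", A + 2, n)
  mu <- colMeans(X_target)
  Xc <- sweep(X_target, 2, mu)
  sv <- svd(Xc, nu = 0)
  eigs <- sv$d^2 / (n - 1)
  rank <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1])
  if (A >= rank + 1 || A > min(n - 1, p))
    fail("A = %d components >= rank %d of the centered data", A, rank)
  P <- sv$v[, seq_len(A), drop = FALSE]
  t2_limit <- A * (n^2 - 1) / (n * (n - A)) * stats::qf(1 - alpha, A, n - A)
  q_limit <- if (length(eigs) > A) q_limit_jm(eigs[-seq_len(A)], alpha)
             else .Machine$double.eps
  structure(list(mean = mu, loadings = P, eigenvalues = eigs, A = A, n = n,
                 q_limit_95 = max(q_limit, .Machine$double.eps),
                 t2_limit_95 = t2_limit,
                 threshold = sqrt(2), alpha = alpha,
                 distance_form = distance_form,
                 target_label = target_label),
            class = "simca_model")
}

#' @export
print.simca_model <- function(x, ...) {
  cat(sprintf("simca_model '%s': A = %d (n = %d), Q95 = %.4g, T2_95 = %.4g, threshold = %.4g\n",
              x$target_label, x$A, x$n, x$q_limit_95, x$t2_limit_95, x$threshold))
  invisible(x)
}

# raw Q and T2 statistics of rows of X under a fitted model
q_t2 <- function(model, X) {
  if (ncol(X) != length(model$mean))
    fail("X has %d variables; model was fitted on %d", ncol(X), length(model$mean))
  Xc <- sweep(X, 2, model$mean)
  Tsc <- Xc %*% model$loadings
  resid <- Xc - Tsc %*% t(model$loadings)
  list(Q = rowSums(resid^2),
       T2 = rowSums(sweep(Tsc^2, 2, model$eigenvalues[seq_len(model$A)], "/")),
       scores = Tsc)
}

#' Reduced distance of samples from a SIMCA class model
#'
#' `d = sqrt((Q / Q95)^2 + (T2 / T2_95)^2)` (or the sum form
#' `Q/Q95 + T2/T2_95` if the model was built with it). A sample is accepted
#' when `d <= threshold`.
#'
#' @param model A `simca_model`.
#' @param X Matrix on the model's variable set.
#' @return Numeric vector of reduced distances.
#' @export
reduced_distance <- function(model, X) {
  stopifnot(inherits(model, "simca_model"))
  s <- q_t2(model, X)
  qn <- s$Q / model$q_limit_95
  tn <- s$T2 / model$t2_limit_95
  if (model$distance_form == "euclidean") sqrt(qn^2 + tn^2) else qn + tn
}

#' @export
#' @describeIn reduced_distance Predict acceptance: returns a data frame with
#'   `Q`, `T2`, `distance` and logical `accepted`.
predict.simca_model <- function(object, newdata, ...) {
  s <- q_t2(object, newdata)
  d <- reduced_distance(object, newdata)
  data.frame(Q = s$Q, T2 = s$T2, distance = d,
             accepted = d <= object$threshold)
}

#' Tune the acceptance threshold from target / non-target distances
#'
#' Exhaustive, deterministic search over the midpoints between adjacent
#' sorted distances (plus one candidate below and above all distances),
#' maximizing sensitivity + specificity. Ties are broken toward higher
#' sensitivity, then toward the smaller threshold.
#'
#' @param d_target Reduced distances of target-class samples (ideally
#'   cross-validated).
#' @param d_nontarget Reduced distances of non-target samples.
#' @return The tuned threshold, with attributes `sensitivity`,
#'   `specificity` (%) at that threshold.
#' @export
optimize_threshold <- function(d_target, d_nontarget) {
  stopifnot(length(d_target) >= 1, length(d_nontarget) >= 1)
  d_all <- sort(unique(c(d_target, d_nontarget)))
  cand <- unique(c(d_all[1] / 2,
                   if (length(d_all) > 1) (d_all[-1] + d_all[-length(d_all)]) / 2,
                   d_all[length(d_all)] * 1.05 + .Machine$double.eps))
  cand <- cand[cand > 0]
  sens <- vapply(cand, function(t) 100 * mean(d_target <= t), numeric(1))
  spec <- vapply(cand, function(t) 100 * mean(d_nontarget > t), numeric(1))
  obj <- sens + spec
  best <- which(obj == max(obj))
  best <- best[sens[best] == max(sens[best])]
  best <- best[which.min(cand[best])]
  structure(cand[best], sensitivity = sens[best], specificity = spec[best])
}

#' Choose the number of SIMCA components by leave-one-out cross-validation
#'
#' For each candidate A, computes a leave-one-out RMSECV and the
#' leave-one-out sensitivity (fraction of left-out target samples accepted
#' at the default sqrt(2) boundary). The RMSECV leaves each sample out of
#' the PCA fit and predicts each of its variables from the remaining
#' variables through the loadings (the naive full-vector projection residual
#' is monotone in A and cannot locate a rank); this leave-one-variable-out
#' prediction has the closed form `e_j = (x_j - r_j) / (1 - h_j)` with `r`
#' the A-component reconstruction and `h_j` the loading leverage of variable
#' j. The chosen A is the smallest whose RMSECV is within 1% of the minimum;
#' exact RMSECV ties are resolved by the higher LOO sensitivity.
#'
#' @param X_target Target-class matrix.
#' @param A_range Candidate component numbers.
#' @return A list with `chosen`, and `diagnostics` (A, rmsecv,
#'   loo_sensitivity).
#' @export
select_n_components <- function(X_target, A_range = 1:5) {
  stopifnot(is.matrix(X_target))
  n <- nrow(X_target)
  A_range <- sort(unique(as.integer(A_range)))
  A_max <- max(A_range)
  if (n < A_max + 2) fail("need at least max(A_range) + 2 = %d rows, got %d", A_max + 2, n)
  press <- matrix(0, n, length(A_range))   # squared LOO prediction error
  accepted <- matrix(NA, n, length(A_range))
  for (i in seq_len(n)) {
    Xtr <- X_target[-i, , drop = FALSE]
    mu <- colMeans(Xtr)
    sv <- svd(sweep(Xtr, 2, mu), nu = 0)
    xi <- X_target[i, ] - mu
    for (a_idx in seq_along(A_range)) {
      A <- A_range[a_idx]
      P <- sv$v[, seq_len(A), drop = FALSE]
      r <- as.vector(P %*% crossprod(P, xi))
      h <- pmin(rowSums(P^2), 1 - 1e-12)
      press[i, a_idx] <- sum(((xi - r) / (1 - h))^2)
      m <- tryCatch(fit_simca(Xtr, A), error = function(e) NULL)
      if (!is.null(m))
        accepted[i, a_idx] <- reduced_distance(m, matrix(X_target[i, ], 1)) <= sqrt(2)
    }
  }
  rmsecv <- sqrt(colMeans(press) / ncol(X_target))
  loo_sens <- 100 * colMeans(accepted, na.rm = TRUE)
  within <- which(rmsecv <= min(rmsecv) * 1.01)
  # smallest A within 1% of the minimum; exact ties resolved by sensitivity
  chosen_idx <- min(within)
  ties <- within[abs(rmsecv[within] - rmsecv[chosen_idx]) <= 1e-12 * max(rmsecv)]
  if (length(ties) > 1) chosen_idx <- ties[which.max(loo_sens[ties])]
  list(chosen = A_range[chosen_idx],
       diagnostics = data.frame(A = A_range, rmsecv = rmsecv,
                                loo_sensitivity = loo_sens))
}

#' Duplex calibration/test split
#'
#' Deterministic duplex assignment on Euclidean distances of the centered
#' data: rounds alternate between the calibration and test sides (calibration
#' first), each round claiming the two mutually farthest remaining points,
#' until the test side holds `ceiling((1 - ratio) * n)` units; all remaining
#' points go to calibration. If the test side needs only one more unit, the
#' member of the farthest pair that is farther from the current test set
#' enters. Replicate measurements of one physical sample are forced to the
#' same side by splitting on replicate-group centroids.
#'
#' @param X Data matrix (rows = measurements).
#' @param ratio Calibration fraction (default 0.8).
#' @param groups Optional vector (length `nrow(X)`) of physical-sample ids;
#'   rows sharing a group never straddle the split.
#' @return A list with integer row indices `calibration` and `test`.
#' @export
duplex_split <- function(X, ratio = 0.8, groups = NULL) {
  stopifnot(is.matrix(X), ratio > 0, ratio < 1)
  if (is.null(groups)) groups <- seq_len(nrow(X))
  groups <- as.character(groups)
  units <- unique(groups)
  n_units <- length(units)
  if (n_units < 5) fail("need at least 5 distinct samples for a duplex split, got %d", n_units)
  U <- vapply(units, function(g)
    colMeans(X[groups == g, , drop = FALSE]), numeric(ncol(X)))
  U <- if (is.matrix(U)) t(U) else matrix(U, ncol = 1)
  U <- sweep(U, 2, colMeans(U))
  D <- as.matrix(stats::dist(U))
  n_test <- ceiling((1 - ratio) * n_units)

  remaining <- seq_len(n_units)
  cal <- integer(0); test <- integer(0)
  side <- "cal"
  while (length(remaining) >= 2 && length(test) < n_test) {
    Dr <- D[remaining, remaining, drop = FALSE]
    idx <- which(Dr == max(Dr), arr.ind = TRUE)[1, ]
    pair <- remaining[sort(idx)]
    if (side == "cal") {
      cal <- c(cal, pair)
      remaining <- setdiff(remaining, pair)
      side <- "test"
    } else {
      need <- n_test - length(test)
      if (need >= 2) {
        test <- c(test, pair)
        remaining <- setdiff(remaining, pair)
      } else {
        # one slot left: take the pair member farther from the current test set
        pick <- if (length(test) == 0) pair[1] else {
          dmin <- vapply(pair, function(u) min(D[u, test]), numeric(1))
          pair[which.max(dmin)]
        }
        test <- c(test, pick)
        remaining <- setdiff(remaining, pick)
      }
      side <- "cal"
    }
  }
  cal <- c(cal, remaining)
  list(calibration = sort(which(groups %in% units[cal])),
       test = sort(which(groups %in% units[test])))
}

#' Flag potential outliers by leverage and Q-residual diagnostics
#'
#' Fits an initial PCA on all rows and flags samples whose leverage exceeds
#' `3 (A + 1) / n` or whose Q residual exceeds its 95% limit. The function
#' only flags: removal is the analyst's decision, never silent.
#'
#' @param X Data matrix.
#' @param n_components Number of PCA components for the screen; default the
#'   smallest number explaining 95% of the variance (at most `n - 2`).
#' @return Data frame with one row per sample: leverage, Q, limits and a
#'   logical `flagged`.
#' @export
screen_outliers <- function(X, n_components = NULL) {
  stopifnot(is.matrix(X))
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0)
  eigs <- sv$d^2 / (n - 1)
  if (is.null(n_components)) {
    cum <- cumsum(eigs) / sum(eigs)
    n_components <- min(which(cum >= 0.95), n - 2, ncol(X))
  }
  A <- max(1L, as.integer(n_components))
  P <- sv$v[, seq_len(A), drop = FALSE]
  Tsc <- Xc %*% P
  lev <- 1 / n + rowSums(sweep(Tsc^2, 2, (n - 1) * eigs[seq_len(A)], "/"))
  Q <- rowSums((Xc - Tsc %*% t(P))^2)
  q95 <- if (length(eigs) > A) q_limit_jm(eigs[-seq_len(A)]) else .Machine$double.eps
  lev_limit <- 3 * (A + 1) / n
  data.frame(row = seq_len(n),
             id = if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(n)),
             leverage = lev, leverage_limit = lev_limit,
             Q = Q, q_limit = q95,
             flagged = lev > lev_limit | Q > q95)
}

#' Classification metrics from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/total, all in percent. An empty class yields `NA` (undefined),
#' never zero.
#'
#' @param TP,FN,TN,FP Confusion counts.
#' @return An object of class `classification_metrics`.
#' @export
classification_metrics <- function(TP, FN, TN, FP) {
  stopifnot(TP >= 0, FN >= 0, TN >= 0, FP >= 0)
  total <- TP + FN + TN + FP
  structure(list(
    TP = TP, FN = FN, TN = TN, FP = FP,
    sensitivity = if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_,
    specificity = if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_,
    accuracy = if (total > 0) 100 * (TP + TN) / total else NA_real_
  ), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%% (TP %d, FN %d, TN %d, FP %d)\n",
              x$accuracy, x$sensitivity, x$specificity, x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

#' Evaluate a one-class model on labelled data
#'
#' Applies the model's accept/reject rule and tabulates the confusion
#' counts against binary labels (target vs rest).
#'
#' @param model A `simca_model` or `mb_occ` model.
#' @param X Data matrix (for `mb_occ`: list of blocks).
#' @param labels Logical (TRUE = target) or character vector compared
#'   against the model's `target_label`.
#' @return A `classification_metrics` object.
#' @export
evaluate <- function(model, X, labels) {
  if (!is.logical(labels)) labels <- labels == model$target_label
  acc <- if (inherits(model, "mb_occ")) predict(model, X)$accepted
         else predict(model, X)$accepted
  if (length(acc) != length(labels)) fail("labels length does not match rows of X")
  classification_metrics(TP = sum(acc & labels), FN = sum(!acc & labels),
                         TN = sum(!acc & !labels), FP = sum(acc & !labels))
}
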