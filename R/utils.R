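#' Derive a per-stage seed from a single study seed
#'
#' A single global seed fans out deterministically to one seed per named
#' pipeline stage, so that changing one stage's seed (by renaming it) leaves
#' the others unchanged and every stage stays reproducible in isolation.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # simple string hash (djb2 variant) folded with the master seed; all
  # arithmetic kept in double but bounded below 2^31
  h <- 5381
  for (ch in utf8ToInt(stage)) h <- (h * 33 + ch) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

#' Tucker congruence between two vectors
#'
#' Cosine of the angle between two loading or score vectors; the standard
#' factor-matching coefficient (scale-free, sign-sensitive).
#'
#' @param a,b Numeric vectors of equal length.
#' @return Congruence in `[-1, 1]`.
#' @export
congruence <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Greedy congruence matching of estimated factors to reference factors
#'
#' Matches columns of estimated factor matrices to reference columns by
#' absolute product of congruences across all supplied modes, greedily from
#' the best pair down. Recovery claims are therefore stated up to permutation
#' and (positive) scaling.
#'
#' @param est,ref Lists of matrices (one per mode), columns = components.
#' @return A list with `perm` (index into est columns for each ref column)
#'   and `congruence` (per-mode matrix of matched congruences, modes x F).
#' @export
match_components <- function(est, ref) {
  stopifnot(length(est) == length(ref))
  f <- ncol(ref[[1]])
  score <- matrix(1, f, f)  # ref x est
  for (m in seq_along(ref)) {
    cm <- crossprod(
      sweep(ref[[m]], 2, sqrt(colSums(ref[[m]]^2)), "/"),
      sweep(est[[m]], 2, sqrt(colSums(est[[m]]^2)), "/")
    )
    score <- score * abs(cm)
  }
  perm <- integer(f)
  avail <- rep(TRUE, f)
  sc <- score
  for (k in seq_len(f)) {
    idx <- which(sc == max(sc), arr.ind = TRUE)[1, ]
    perm[idx[1]] <- idx[2]
    sc[idx[1], ] <- -Inf
    sc[, idx[2]] <- -Inf
  }
  cong <- vapply(seq_along(ref), function(m) {
    vapply(seq_len(f), function(k) {
      congruence(ref[[m]][, k], est[[m]][, perm[k]])
    }, numeric(1))
  }, numeric(f))
  list(perm = perm, congruence = t(cong))
}

# internal: stop with a formatted message
fail <- function(...) stop(sprintf(...), call. = FALSE)
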