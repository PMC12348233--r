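#' Construct a 1-D NMR spectrum
#'
#' A processed (phased, baseline-corrected) proton spectrum: a strictly
#' monotone ppm axis and non-negative intensities, tagged with sample and
#' replicate identifiers.
#'
#' @param ppm Numeric axis (ppm), strictly monotone increasing.
#' @param intensity Non-negative intensities, same length as `ppm`.
#' @param sample_id,replicate_id Identifiers.
#' @return An object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, intensity, sample_id = "S1", replicate_id = 1L) {
  if (length(ppm) != length(intensity))
    fail("ppm and intensity lengths differ (%d vs %d)", length(ppm), length(intensity))
  if (any(diff(ppm) <= 0)) fail("ppm axis must be strictly monotone increasing")
  if (any(intensity < 0)) fail("intensities must be non-negative")
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 sample_id = as.character(sample_id),
                 replicate_id = replicate_id),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("nmr_spectrum %s (replicate %s): %d points, %.2f-%.2f ppm\n",
              x$sample_id, x$replicate_id, length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

# trapezoidal integral of a piecewise-linear spectrum over [a, b],
# with exact linear interpolation at the interval edges
segment_area <- function(ppm, intensity, a, b) {
  inside <- ppm > a & ppm < b
  xs <- c(a, ppm[inside], b)
  ys <- stats::approx(ppm, intensity, xout = xs, rule = 1)$y
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Bucket spectra into a sample x ppm-interval table
#'
#' Sections each spectrum into regular ppm intervals ("buckets") and
#' integrates the intensity over each. Buckets are left-closed, right-open,
#' anchored at the lower range edge; a trailing partial bucket is dropped.
#' Any bucket whose interval intersects an exclusion region (by default the
#' residual water band 4.50-5.20 ppm and the residual methanol band
#' 3.28-3.40 ppm) is removed whole, so excluded signal is never mixed into a
#' retained feature.
#'
#' @param spectra A list of [nmr_spectrum()] objects (or a single one).
#' @param width Bucket width (ppm), default 0.04.
#' @param range Bucketing range (ppm), default `c(0.50, 10.00)`.
#' @param exclusions List of length-2 ppm intervals to exclude; default the
#'   water and methanol residual regions.
#' @return An object of class `bucket_table`: integrated (un-normalized)
#'   areas, samples x retained buckets, with bucket edges, exclusion record
#'   and per-row full-range totals (used by the alternative normalization
#'   order of [normalize_total()]).
#' @export
bucket <- function(spectra, width = 0.04, range = c(0.50, 10.00),
                   exclusions = list(c(4.50, 5.20), c(3.28, 3.40))) {
  if (inherits(spectra, "nmr_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1, width > 0, range[2] > range[1])
  n_full <- floor((range[2] - range[1]) / width + 1e-9)
  lower <- range[1] + width * (seq_len(n_full) - 1)
  upper <- lower + width
  center <- (lower + upper) / 2

  excluded <- rep(FALSE, n_full)
  for (ex in exclusions) {
    if (length(ex) != 2 || ex[2] <= ex[1]) fail("exclusion regions must be increasing intervals")
    excluded <- excluded | (lower < ex[2] & upper > ex[1])
  }

  mat_full <- matrix(NA_real_, length(spectra), n_full)
  row_ids <- character(length(spectra))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    stopifnot(inherits(s, "nmr_spectrum"))
    if (min(s$ppm) > range[1] || max(s$ppm) < range[2])
      fail("spectrum %s covers %.3f-%.3f ppm; bucketing range %.2f-%.2f not covered",
           s$sample_id, min(s$ppm), max(s$ppm), range[1], range[2])
    for (k in seq_len(n_full))
      mat_full[i, k] <- segment_area(s$ppm, s$intensity, lower[k], upper[k])
    row_ids[i] <- sprintf("%s_r%s", s$sample_id, s$replicate_id)
  }
  keep <- !excluded
  mat <- mat_full[, keep, drop = FALSE]
  rownames(mat) <- row_ids
  colnames(mat) <- sprintf("%.3f", center[keep])
  structure(list(
    matrix = mat,
    bucket_edges = data.frame(lower = lower[keep], upper = upper[keep],
                              center = center[keep]),
    excluded_regions = exclusions,
    row_ids = row_ids,
    row_total_full = rowSums(mat_full),
    sample_id = vapply(spectra, `[[`, "", "sample_id"),
    replicate_id = vapply(spectra, function(s) as.integer(s$replicate_id), 1L),
    normalized = FALSE
  ), class = "bucket_table")
}

#' @export
print.bucket_table <- function(x, ...) {
  cat(sprintf("bucket_table: %d rows x %d buckets (%.3f ppm wide)%s\n",
              nrow(x$matrix), ncol(x$matrix),
              x$bucket_edges$upper[1] - x$bucket_edges$lower[1],
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Normalize each bucket row to total intensity
#'
#' Divides every row by its own total so rows sum to one (default: total
#' over the retained buckets, i.e. after solvent-region exclusion). The
#' `"full"` switch instead divides by the pre-exclusion full-range total;
#' the two orders differ only by a per-row scale and give identical rows
#' after re-normalization.
#'
#' @param bt A [bucket_table()].
#' @param total `"retained"` (default) or `"full"`.
#' @return The normalized `bucket_table`.
#' @export
normalize_total <- function(bt, total = c("retained", "full")) {
  stopifnot(inherits(bt, "bucket_table"))
  total <- match.arg(total)
  tot <- if (total == "retained") rowSums(bt$matrix) else bt$row_total_full
  bad <- which(!(tot > 0))
  if (length(bad))
    fail("non-positive row total for sample(s): %s",
         paste(bt$row_ids[bad], collapse = ", "))
  bt$matrix <- bt$matrix / tot
  bt$normalized <- TRUE
  bt
}

#' Mean-center a data matrix (optionally against reference means)
#'
#' Subtracts column means. For projecting a test set into a model built on
#' centered training data, pass the training means as `reference_means`.
#' The means used are attached as attribute `"means"`.
#'
#' @param x Numeric matrix (or `bucket_table`, centered in place).
#' @param reference_means Optional numeric vector of column means to use.
#' @return Centered matrix with attribute `"means"`.
#' @export
mean_center <- function(x, reference_means = NULL) {
  if (inherits(x, "bucket_table")) {
    x$matrix <- mean_center(x$matrix, reference_means)
    return(x)
  }
  stopifnot(is.matrix(x), nrow(x) >= 1)
  m <- if (is.null(reference_means)) colMeans(x) else as.numeric(reference_means)
  if (length(m) != ncol(x))
    fail("reference_means has length %d; matrix has %d columns", length(m), ncol(x))
  out <- sweep(x, 2, m)
  attr(out, "means") <- m
  out
}
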