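#' Subtract a blank EEM from every sample
#'
#' Removes the solvent background by subtracting a blank excitation-emission
#' matrix, recorded on the same wavelength grid, from every sample slab.
#' The missing-value mask is preserved.
#'
#' @param cube An [eem_cube()].
#' @param blank Numeric emission x excitation matrix on the cube's grid, or
#'   a single-sample `eem_cube` (axes are then checked for equality).
#' @return The blank-subtracted `eem_cube`.
#' @export
subtract_blank <- function(cube, blank) {
  stopifnot(inherits(cube, "eem_cube"))
  if (inherits(blank, "eem_cube")) {
    if (!isTRUE(all.equal(blank$em_axis, cube$em_axis)) ||
        !isTRUE(all.equal(blank$ex_axis, cube$ex_axis)))
      fail("blank grid differs from cube grid (em: %g-%g vs %g-%g; ex: %g-%g vs %g-%g)",
           min(blank$em_axis), max(blank$em_axis), min(cube$em_axis), max(cube$em_axis),
           min(blank$ex_axis), max(blank$ex_axis), min(cube$ex_axis), max(cube$ex_axis))
    blank <- blank$data[1, , ]
  }
  d <- dim(cube$data)
  if (!identical(dim(blank), d[2:3]))
    fail("blank is %d x %d; cube slabs are %d emission x %d excitation",
         nrow(blank), ncol(blank), d[2], d[3])
  for (i in seq_len(d[1])) cube$data[i, , ] <- cube$data[i, , ] - blank
  cube
}

#' Flag Rayleigh and Raman scatter bands as missing
#'
#' Masks all points within a bandwidth of the first-order Rayleigh line
#' (emission = excitation), the second-order Rayleigh line (emission = 2 x
#' excitation) and the solvent Raman line (offset from the excitation line
#' by a fixed wavenumber shift). The physically meaningless region below the
#' first-order Rayleigh line (emission < excitation) is set to zero by
#' default rather than interpolated.
#'
#' @param cube An [eem_cube()].
#' @param bandwidths Named list of half-bandwidths (nm): `rayleigh1`,
#'   `raman`, `rayleigh2`. Defaults 10 / 10 / 15 nm.
#' @param raman_shift_cm1 Raman shift (cm^-1), default 3400 (water-like OH
#'   stretch of the methanol/water solvent).
#' @param below_rayleigh `"zero"` (default), `"mask"` or `"keep"` for the
#'   region below the first-order Rayleigh band.
#' @return The cube with scatter points masked (values set `NA`).
#' @export
remove_scatter <- function(cube,
                           bandwidths = list(rayleigh1 = 10, raman = 10, rayleigh2 = 15),
                           raman_shift_cm1 = 3400,
                           below_rayleigh = c("zero", "mask", "keep")) {
  stopifnot(inherits(cube, "eem_cube"))
  below_rayleigh <- match.arg(below_rayleigh)
  bw <- bandwidths
  if (any(unlist(bw) < 0)) fail("scatter bandwidths must be >= 0")
  em <- cube$em_axis; ex <- cube$ex_axis
  raman_em <- 1 / (1 / ex - raman_shift_cm1 * 1e-7)

  band <- matrix(FALSE, length(em), length(ex))
  below <- matrix(FALSE, length(em), length(ex))
  for (j in seq_along(ex)) {
    band[, j] <- abs(em - ex[j]) <= bw$rayleigh1 |
      abs(em - 2 * ex[j]) <= bw$rayleigh2 |
      abs(em - raman_em[j]) <= bw$raman
    below[, j] <- em < ex[j] - bw$rayleigh1
  }
  for (i in seq_len(dim(cube$data)[1])) {
    slab <- cube$data[i, , ]
    slab[band] <- NA_real_
    if (below_rayleigh == "zero") slab[below] <- 0
    if (below_rayleigh == "mask") slab[below] <- NA_real_
    cube$data[i, , ] <- slab
    m <- cube$mask[i, , ]
    m[band] <- TRUE
    if (below_rayleigh == "mask") m[below] <- TRUE
    cube$mask[i, , ] <- m
  }
  cube
}

#' Fill masked EEM values by shape-preserving interpolation
#'
#' Replaces flagged values by monotone (shape-preserving) cubic Hermite
#' interpolation along the emission mode within each excitation column of
#' each sample, clipping at zero. Columns with fewer than two observed
#' points cannot be interpolated: they are left missing and reported in the
#' attribute `"unfilled"`.
#'
#' @param cube An [eem_cube()] with a mask set (see [remove_scatter()]).
#' @return The interpolated cube (mask cleared where filled), with attribute
#'   `"unfilled"`: a data frame of sample/excitation columns left missing.
#' @export
interpolate_missing <- function(cube) {
  stopifnot(inherits(cube, "eem_cube"))
  em <- cube$em_axis
  unfilled <- list()
  for (i in seq_len(dim(cube$data)[1])) {
    for (j in seq_along(cube$ex_axis)) {
      miss <- cube$mask[i, , j]
      if (!any(miss)) next
      obs <- which(!miss & !is.na(cube$data[i, , j]))
      if (length(obs) < 2) {
        unfilled[[length(unfilled) + 1L]] <-
          data.frame(sample = cube$sample_ids[i], ex = cube$ex_axis[j])
        next
      }
      f <- stats::splinefun(em[obs], cube$data[i, obs, j], method = "monoH.FC")
      cube$data[i, miss, j] <- pmax(f(em[miss]), 0)
      cube$mask[i, miss, j] <- FALSE
    }
  }
  attr(cube, "unfilled") <- if (length(unfilled)) do.call(rbind, unfilled) else NULL
  if (length(unfilled))
    warning(sprintf("%d excitation column(s) had < 2 observed points and were left missing",
                    length(unfilled)), call. = FALSE)
  cube
}

#' Normalize each sample slab to unit variance
#'
#' Divides every sample's EEM by the standard deviation of its own entries,
#' so all samples carry the same total variance (sample-mode unit-variance
#' normalization). Scalar-multiple samples become identical.
#'
#' @param cube An [eem_cube()] (no missing values).
#' @return The normalized cube.
#' @export
normalize_sample_variance <- function(cube) {
  stopifnot(inherits(cube, "eem_cube"))
  for (i in seq_len(dim(cube$data)[1])) {
    s <- stats::sd(as.vector(cube$data[i, , ]), na.rm = TRUE)
    if (!is.finite(s) || s <= 0)
      fail("sample %s has zero variance; cannot normalize", cube$sample_ids[i])
    cube$data[i, , ] <- cube$data[i, , ] / s
  }
  cube
}
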