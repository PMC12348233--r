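#' Construct an EEM cube
#'
#' Container for a set of excitation-emission matrices: a 3-way array with
#' fixed mode order samples x emission x excitation, wavelength axes, a
#' logical missing-value mask aligned with the data (TRUE = flagged missing,
#' e.g. inside scatter bands) and sample identifiers.
#'
#' @param data Numeric array, samples x emission x excitation.
#' @param em_axis,ex_axis Strictly increasing wavelength axes (nm).
#' @param sample_ids Character vector, one id per sample slab.
#' @param mask Logical array of the same dimension as `data`; default no
#'   missing values.
#' @return An object of class `eem_cube`.
#' @export
eem_cube <- function(data, em_axis, ex_axis, sample_ids = NULL, mask = NULL) {
  d <- dim(data)
  if (length(d) != 3) fail("data must be a 3-way array (samples x emission x excitation)")
  if (d[2] != length(em_axis) || d[3] != length(ex_axis))
    fail("axis lengths (%d em, %d ex) do not match data dims (%d, %d)",
         length(em_axis), length(ex_axis), d[2], d[3])
  if (any(diff(em_axis) <= 0) || any(diff(ex_axis) <= 0))
    fail("wavelength axes must be strictly increasing")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(d[1]))
  if (length(sample_ids) != d[1]) fail("need one sample id per slab")
  if (is.null(mask)) mask <- array(FALSE, dim = d)
  if (!identical(dim(mask), d)) fail("mask dimensions must match data")
  structure(list(data = data, em_axis = as.numeric(em_axis),
                 ex_axis = as.numeric(ex_axis),
                 sample_ids = as.character(sample_ids),
                 mask = mask),
            class = "eem_cube")
}

#' @export
print.eem_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("eem_cube: %d samples x %d emission (%g-%g nm) x %d excitation (%g-%g nm)\n",
              d[1], d[2], min(x$em_axis), max(x$em_axis),
              d[3], min(x$ex_axis), max(x$ex_axis)))
  cat(sprintf("  masked: %d / %d values\n", sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @export
dim.eem_cube <- function(x) dim(x$data)

#' Specify a rectangular excitation/emission region
#'
#' Used to split an EEM landscape into spectral regions, e.g. the chlorophyll
#' region of leaf extracts (Region A: excitation 300-700 nm, emission
#' 650-750 nm) versus the cellular-fluorophore region (Region B: excitation
#' 250-400 nm, emission 370-530 nm).
#'
#' @param ex_range,em_range Length-2 numeric intervals (nm).
#' @param name Region label.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(ex_range, em_range, name = "region") {
  stopifnot(length(ex_range) == 2, length(em_range) == 2)
  if (ex_range[2] < ex_range[1] || em_range[2] < em_range[1])
    fail("region ranges must be increasing intervals")
  structure(list(ex_range = as.numeric(ex_range), em_range = as.numeric(em_range),
                 name = name), class = "region_spec")
}

#' Crop an EEM cube to a spectral region
#'
#' Restricts both wavelength axes to the region; used to exclude the
#' chlorophyll emission region before classification.
#'
#' @param cube An [eem_cube()].
#' @param region A [region_spec()].
#' @return The cropped `eem_cube`.
#' @export
crop_region <- function(cube, region) {
  stopifnot(inherits(cube, "eem_cube"), inherits(region, "region_spec"))
  keep_em <- cube$em_axis >= region$em_range[1] & cube$em_axis <= region$em_range[2]
  keep_ex <- cube$ex_axis >= region$ex_range[1] & cube$ex_axis <= region$ex_range[2]
  if (!any(keep_em) || !any(keep_ex))
    fail("region '%s' does not intersect the cube axes", region$name)
  eem_cube(cube$data[, keep_em, keep_ex, drop = FALSE],
           cube$em_axis[keep_em], cube$ex_axis[keep_ex],
           cube$sample_ids,
           cube$mask[, keep_em, keep_ex, drop = FALSE])
}

#' Unfold an EEM cube into a samples x (emission.excitation) matrix
#'
#' The unfolding is a fixed bijection with the emission index running
#' fastest: column `(j - 1) * n_em + i` of the matrix holds emission i /
#' excitation j. [refold()] inverts it exactly. Column names record the
#' wavelength pair as `em<em>_ex<ex>`.
#'
#' @param cube An [eem_cube()].
#' @return Numeric matrix, samples x (n_em * n_ex).
#' @export
unfold <- function(cube) {
  stopifnot(inherits(cube, "eem_cube"))
  d <- dim(cube$data)
  out <- matrix(aperm(cube$data, c(2, 3, 1)), nrow = d[1], byrow = TRUE)
  rownames(out) <- cube$sample_ids
  colnames(out) <- as.vector(outer(cube$em_axis, cube$ex_axis,
                                   function(em, ex) sprintf("em%g_ex%g", em, ex)))
  out
}

#' Refold an unfolded vector into an emission x excitation matrix
#'
#' Inverse of the [unfold()] bijection for one sample (or one loading
#' vector): emission index fastest.
#'
#' @param v Numeric vector of length `length(em_axis) * length(ex_axis)`.
#' @param em_axis,ex_axis Wavelength axes of the original cube.
#' @return Numeric matrix, emission x excitation, with axes as dimnames.
#' @export
refold <- function(v, em_axis, ex_axis) {
  if (length(v) != length(em_axis) * length(ex_axis))
    fail("vector length %d != %d emission x %d excitation",
         length(v), length(em_axis), length(ex_axis))
  matrix(as.numeric(v), nrow = length(em_axis), ncol = length(ex_axis),
         dimnames = list(em = as.character(em_axis), ex = as.character(ex_axis)))
}
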