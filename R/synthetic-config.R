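#' Specify one NMR peak
#'
#' A single Lorentzian line: the natural NMR lineshape, parameterized by its
#' center (chemical shift), half-width at half-maximum and relative area.
#'
#' @param center Chemical shift of the peak maximum (ppm).
#' @param width Half-width at half-maximum (ppm), > 0.
#' @param relative_area Dimensionless area weight, >= 0.
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(center, width = 0.01, relative_area = 1) {
  if (!is.finite(width) || width <= 0) fail("peak width must be > 0 (got %g)", width)
  if (!is.finite(relative_area) || relative_area < 0)
    fail("relative_area must be >= 0 (got %g)", relative_area)
  structure(list(center = center, width = width, relative_area = relative_area),
            class = "peak_spec")
}

#' Specify one metabolite for the NMR generator
#'
#' A metabolite is a set of peaks plus a per-class concentration model:
#' concentrations are drawn log-normally, `exp(N(class_log_mean, sdlog))`,
#' which guarantees positivity and expresses class effects as fold changes.
#'
#' @param name Metabolite name.
#' @param peaks List of [peak_spec()] objects.
#' @param class_log_mean Numeric vector, one log-scale mean per class.
#' @param sdlog Between-sample standard deviation on the log scale.
#' @return An object of class `metabolite_spec`.
#' @export
metabolite_spec <- function(name, peaks, class_log_mean, sdlog = 0.2) {
  stopifnot(is.character(name), length(peaks) >= 1)
  peaks <- lapply(peaks, function(p) if (inherits(p, "peak_spec")) p else do.call(peak_spec, p))
  if (sdlog < 0) fail("sdlog must be >= 0")
  structure(list(name = name, peaks = peaks,
                 class_log_mean = as.numeric(class_log_mean), sdlog = sdlog),
            class = "metabolite_spec")
}

#' Specify one fluorophore for the EEM generator
#'
#' Gaussian excitation and emission profiles (unit maximum); the trilinear
#' contribution of the fluorophore to a sample's EEM is
#' `abundance * em_profile %o% ex_profile`. Abundances are drawn log-normally
#' around a per-class mean.
#'
#' @param name Fluorophore name.
#' @param ex_center,em_center Excitation / emission maxima (nm).
#' @param ex_width,em_width Gaussian standard deviations (nm), > 0.
#' @param mean_abundance Numeric vector, one mean abundance per class (>= 0).
#' @param sdlog Between-sample log-scale standard deviation.
#' @return An object of class `fluorophore_spec`.
#' @export
fluorophore_spec <- function(name, ex_center, em_center, ex_width = 20,
                             em_width = 30, mean_abundance = 1, sdlog = 0.25) {
  if (ex_width <= 0 || em_width <= 0) fail("fluorophore widths must be > 0")
  if (any(mean_abundance < 0)) fail("mean_abundance must be >= 0")
  structure(list(name = name, ex_center = ex_center, em_center = em_center,
                 ex_width = ex_width, em_width = em_width,
                 mean_abundance = as.numeric(mean_abundance), sdlog = sdlog),
            class = "fluorophore_spec")
}

#' Default olive-leaf metabolite library
#'
#' Marker set for leaf extracts of *Olea europaea*: the secoiridoid
#' oleuropein/ligstroside resonances at 1.64, 2.80, 3.71 and 6.73 ppm,
#' mannitol (3.65, 3.81 ppm), glucose anomeric and ring protons (3.37,
#' 4.53 ppm), quinic acid (1.96 ppm) and the triterpenic maslinic/oleanolic
#' acids (0.90-1.13 ppm), plus residual water (4.79 ppm) and methanol
#' (3.31 ppm) solvent lines sitting inside the standard exclusion regions.
#' Class effects (three geographic classes) are expressed as log-scale mean
#' shifts of the secoiridoid, sugar and organic-acid pools.
#'
#' @param n_classes Number of classes the class-mean vectors must cover.
#' @return List of [metabolite_spec()] objects.
#' @export
default_metabolite_library <- function(n_classes = 3) {
  rep_to <- function(x) rep_len(x, n_classes)
  list(
    metabolite_spec("oleuropein",
      peaks = list(peak_spec(1.64, 0.012, 1.0), peak_spec(2.80, 0.012, 1.0),
                   peak_spec(3.71, 0.012, 2.0), peak_spec(6.73, 0.012, 1.0)),
      class_log_mean = rep_to(c(log(3.0), log(1.6), log(2.2))), sdlog = 0.20),
    metabolite_spec("mannitol",
      peaks = list(peak_spec(3.65, 0.012, 3.0), peak_spec(3.81, 0.012, 3.0)),
      class_log_mean = rep_to(c(log(4.0), log(5.5), log(4.8))), sdlog = 0.15),
    metabolite_spec("glucose",
      peaks = list(peak_spec(3.37, 0.012, 2.0), peak_spec(4.53, 0.010, 1.0)),
      class_log_mean = rep_to(c(log(3.0), log(3.0), log(3.6))), sdlog = 0.15),
    metabolite_spec("quinic_acid",
      peaks = list(peak_spec(1.96, 0.012, 1.0)),
      class_log_mean = rep_to(c(log(1.0), log(1.5), log(1.2))), sdlog = 0.20),
    metabolite_spec("triterpenic_acids",
      peaks = list(peak_spec(0.90, 0.015, 2.0), peak_spec(1.13, 0.015, 2.0)),
      class_log_mean = rep_to(c(log(1.2), log(1.2), log(0.8))), sdlog = 0.20),
    # solvent residuals: identical in every class, low variability; their ppm
    # regions are excluded during bucketing
    metabolite_spec("water_residual",
      peaks = list(peak_spec(4.79, 0.060, 30.0)),
      class_log_mean = rep_to(log(1.0)), sdlog = 0.05),
    metabolite_spec("methanol_residual",
      peaks = list(peak_spec(3.31, 0.015, 12.0)),
      class_log_mean = rep_to(log(1.0)), sdlog = 0.05)
  )
}

#' Default fluorophore libraries
#'
#' `default_fluorophore_library("leaf")` models the non-pigment emission
#' region of olive leaves (Region B): chlorogenic acid (ex 320 / em 435 nm),
#' phenolic compounds (ex 280 nm, emission maximum below 370 nm) and
#' tocopherols (ex 360 / em 465 nm). `"drupe"` models olive drupe extracts:
#' catechin/epicatechin (280/315 nm), tocopherols (340/450 nm) and phenolic
#' compounds (230/310 nm); note the drupe library requires an excitation axis
#' reaching below 230 nm (see [synthetic_config()]).
#'
#' @param matrix_type `"leaf"` or `"drupe"`.
#' @param n_classes Number of classes for the abundance vectors.
#' @return List of [fluorophore_spec()] objects.
#' @export
default_fluorophore_library <- function(matrix_type = c("leaf", "drupe"),
                                        n_classes = 3) {
  matrix_type <- match.arg(matrix_type)
  rep_to <- function(x) rep_len(x, n_classes)
  if (matrix_type == "leaf") {
    list(
      fluorophore_spec("chlorogenic_acid", 320, 435, 22, 32,
                       rep_to(c(5.0, 3.2, 4.0)), sdlog = 0.25),
      fluorophore_spec("phenolic_compounds", 280, 350, 18, 28,
                       rep_to(c(3.0, 2.0, 2.4)), sdlog = 0.25),
      fluorophore_spec("tocopherols", 360, 465, 24, 34,
                       rep_to(c(1.5, 1.5, 1.5)), sdlog = 0.25)
    )
  } else {
    list(
      fluorophore_spec("catechin_epicatechin", 280, 315, 18, 26,
                       rep_to(c(5.0, 3.5, 4.2)), sdlog = 0.25),
      fluorophore_spec("tocopherols", 340, 450, 24, 34,
                       rep_to(c(2.0, 2.0, 2.0)), sdlog = 0.25),
      fluorophore_spec("phenolic_compounds", 230, 310, 16, 24,
                       rep_to(c(1.5, 1.0, 1.2)), sdlog = 0.25)
    )
  }
}

#' Build and validate a synthetic-study configuration
#'
#' Bundles everything the generators need: design sizes (classes, samples per
#' class, replicate measurements per sample), the metabolite and fluorophore
#' libraries, axes, noise level and scatter-ridge amplitudes, and the RNG
#' seed. A fixed configuration (including seed) regenerates bit-identical
#' data.
#'
#' @param n_classes Number of geographic classes (default 3).
#' @param n_samples_per_class Samples per class (default 10).
#' @param n_replicates Replicate measurements per sample (default 3,
#'   triplicate acquisition); replicates share the sample's concentration /
#'   abundance vector and differ only by instrumental noise.
#' @param metabolites List of [metabolite_spec()]; default
#'   [default_metabolite_library()].
#' @param fluorophores List of [fluorophore_spec()]; default leaf Region-B
#'   library.
#' @param class_names Optional class labels.
#' @param ppm_range,ppm_res NMR axis: range (ppm) and point spacing.
#' @param ex_axis,em_axis EEM wavelength grids (nm), strictly increasing.
#' @param noise_sd Additive Gaussian noise standard deviation, as a fraction
#'   of the maximum noiseless signal (applies to both blocks).
#' @param scatter Named list of scatter ridge amplitudes relative to the
#'   maximum fluorescence signal: `rayleigh1`, `rayleigh2`, `raman`.
#' @param raman_shift_cm1 Raman shift of the solvent band (cm^-1); the ridge
#'   sits at the emission wavelength offset from each excitation wavelength
#'   by this wavenumber.
#' @param rng_seed Integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes = 3,
                             n_samples_per_class = 10,
                             n_replicates = 3,
                             metabolites = default_metabolite_library(n_classes),
                             fluorophores = default_fluorophore_library("leaf", n_classes),
                             class_names = NULL,
                             ppm_range = c(0, 10.5),
                             ppm_res = 0.005,
                             ex_axis = seq(250, 450, by = 10),
                             em_axis = seq(250, 530, by = 2),
                             noise_sd = 0.005,
                             scatter = list(rayleigh1 = 2, rayleigh2 = 0.5, raman = 0.3),
                             raman_shift_cm1 = 3400,
                             rng_seed = 1L) {
  if (n_classes < 1 || n_samples_per_class < 1 || n_replicates < 1)
    fail("all design counts must be >= 1")
  if (noise_sd < 0) fail("noise_sd must be >= 0")
  if (any(unlist(scatter) < 0)) fail("scatter amplitudes must be >= 0")
  if (ppm_res <= 0 || ppm_range[2] <= ppm_range[1]) fail("invalid ppm axis")
  if (any(diff(ex_axis) <= 0) || any(diff(em_axis) <= 0))
    fail("wavelength axes must be strictly increasing")
  if (is.null(class_names))
    class_names <- c("chianti_siena", "grosseto", "val_dorcia",
                     paste0("class_", seq_len(max(0, n_classes - 3)) + 3))[seq_len(n_classes)]

  ppm <- seq(ppm_range[1], ppm_range[2], by = ppm_res)
  for (m in metabolites) {
    if (length(m$class_log_mean) != n_classes)
      fail("metabolite '%s': class_log_mean has length %d, need %d",
           m$name, length(m$class_log_mean), n_classes)
    for (p in m$peaks)
      if (p$center < ppm_range[1] || p$center > ppm_range[2])
        fail("metabolite '%s': peak center %.2f ppm outside axis [%.2f, %.2f]",
             m$name, p$center, ppm_range[1], ppm_range[2])
  }
  for (f in fluorophores) {
    if (length(f$mean_abundance) != n_classes)
      fail("fluorophore '%s': mean_abundance has length %d, need %d",
           f$name, length(f$mean_abundance), n_classes)
    if (f$ex_center < min(ex_axis) || f$ex_center > max(ex_axis))
      fail("fluorophore '%s': excitation center %g nm outside grid [%g, %g]",
           f$name, f$ex_center, min(ex_axis), max(ex_axis))
    if (f$em_center < min(em_axis) || f$em_center > max(em_axis))
      fail("fluorophore '%s': emission center %g nm outside grid [%g, %g]",
           f$name, f$em_center, min(em_axis), max(em_axis))
  }
  structure(list(
    n_classes = as.integer(n_classes),
    n_samples_per_class = as.integer(n_samples_per_class),
    n_replicates = as.integer(n_replicates),
    metabolites = metabolites, fluorophores = fluorophores,
    class_names = class_names,
    ppm = ppm, ppm_range = ppm_range, ppm_res = ppm_res,
    ex_axis = as.numeric(ex_axis), em_axis = as.numeric(em_axis),
    noise_sd = noise_sd, scatter = scatter,
    raman_shift_cm1 = raman_shift_cm1,
    rng_seed = as.integer(rng_seed)
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("synthetic_config: %d classes x %d samples x %d replicates\n",
              x$n_classes, x$n_samples_per_class, x$n_replicates))
  cat(sprintf("  NMR axis: %.2f-%.2f ppm @ %.3f; %d metabolites\n",
              x$ppm_range[1], x$ppm_range[2], x$ppm_res, length(x$metabolites)))
  cat(sprintf("  EEM grid: ex %g-%g nm (%d) x em %g-%g nm (%d); %d fluorophores\n",
              min(x$ex_axis), max(x$ex_axis), length(x$ex_axis),
              min(x$em_axis), max(x$em_axis), length(x$em_axis),
              length(x$fluorophores)))
  cat(sprintf("  noise_sd = %g, seed = %d\n", x$noise_sd, x$rng_seed))
  invisible(x)
}
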