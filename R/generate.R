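#' @keywords internal
lorentzian <- function(x, center, hwhm) {
  (hwhm / pi) / ((x - center)^2 + hwhm^2)
}

# metadata table for one synthetic design: one row per measurement
build_metadata <- function(config) {
  cls <- rep(config$class_names, each = config$n_samples_per_class)
  samp <- sprintf("%s_%02d", toupper(substr(cls, 1, 2)),
                  rep(seq_len(config$n_samples_per_class), config$n_classes))
  samp <- make.unique(samp, sep = "_")
  data.frame(
    measurement_id = sprintf("%s_r%d", rep(samp, each = config$n_replicates),
                             rep(seq_len(config$n_replicates),
                                 config$n_classes * config$n_samples_per_class)),
    sample_id = rep(samp, each = config$n_replicates),
    class = rep(cls, each = config$n_replicates),
    replicate_id = rep(seq_len(config$n_replicates),
                       config$n_classes * config$n_samples_per_class),
    stringsAsFactors = FALSE
  )
}

#' Generate class-structured synthetic 1H NMR spectra
#'
#' Each sample draws one concentration per metabolite from a log-normal with
#' its class's log-mean; every replicate measurement shares the sample's
#' concentration vector and differs only by additive Gaussian noise. A
#' spectrum is the concentration-weighted sum of Lorentzian peak templates
#' (each metabolite's template has total area equal to the sum of its peaks'
#' relative areas), including solvent residual lines inside the standard
#' exclusion regions. Negative noisy intensities are clipped at zero.
#'
#' @param config A [synthetic_config()].
#' @return A list with `spectra` (list of `nmr_spectrum` objects, one per
#'   measurement), `metadata` (data frame) and `true_concentrations`
#'   (samples x metabolites matrix of the drawn concentrations).
#' @export
generate_nmr <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(stage_seed(config$rng_seed, "generate_nmr"))
  meta <- build_metadata(config)
  samples <- unique(meta$sample_id)
  n_samp <- length(samples)
  ppm <- config$ppm

  # per-metabolite spectral templates (unit concentration)
  templates <- vapply(config$metabolites, function(m) {
    tpl <- numeric(length(ppm))
    for (p in m$peaks) tpl <- tpl + p$relative_area * lorentzian(ppm, p$center, p$width)
    tpl
  }, numeric(length(ppm)))
  colnames(templates) <- vapply(config$metabolites, `[[`, "", "name")

  class_of_sample <- meta$class[match(samples, meta$sample_id)]
  class_idx <- match(class_of_sample, config$class_names)
  conc <- matrix(NA_real_, n_samp, length(config$metabolites),
                 dimnames = list(samples, colnames(templates)))
  for (j in seq_along(config$metabolites)) {
    m <- config$metabolites[[j]]
    conc[, j] <- exp(stats::rnorm(n_samp, m$class_log_mean[class_idx], m$sdlog))
  }

  clean <- conc %*% t(templates)        # samples x ppm
  peak_max <- max(clean)
  spectra <- vector("list", nrow(meta))
  for (k in seq_len(nrow(meta))) {
    i <- match(meta$sample_id[k], samples)
    y <- clean[i, ]
    if (config$noise_sd > 0)
      y <- pmax(y + stats::rnorm(length(ppm), 0, config$noise_sd * peak_max), 0)
    spectra[[k]] <- nmr_spectrum(ppm, y, sample_id = meta$sample_id[k],
                                 replicate_id = meta$replicate_id[k])
  }
  names(spectra) <- meta$measurement_id
  list(spectra = spectra, metadata = meta, true_concentrations = conc)
}

#' Generate a synthetic trilinear EEM cube
#'
#' Builds each sample's excitation-emission matrix as the trilinear sum over
#' fluorophores of `abundance x em_profile %o% ex_profile` (Gaussian
#' profiles, unit maximum), then adds first- and second-order Rayleigh
#' ridges (at em = ex and em = 2 ex), a Raman ridge offset from the
#' excitation line by a fixed wavenumber shift, and additive noise.
#' Abundances are log-normal around the fluorophore's class mean; replicates
#' share the sample's abundance vector.
#'
#' @param config A [synthetic_config()].
#' @return A list with `cube` (an [eem_cube()], one slab per measurement),
#'   `metadata`, and `true_factors`: list of `scores` (measurements x F
#'   abundances), `em_loadings`, `ex_loadings` (unit-maximum profiles).
#' @export
generate_eem <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(stage_seed(config$rng_seed, "generate_eem"))
  meta <- build_metadata(config)
  samples <- unique(meta$sample_id)
  em <- config$em_axis; ex <- config$ex_axis
  n_f <- length(config$fluorophores)

  em_load <- vapply(config$fluorophores, function(f)
    exp(-0.5 * ((em - f$em_center) / f$em_width)^2), numeric(length(em)))
  ex_load <- vapply(config$fluorophores, function(f)
    exp(-0.5 * ((ex - f$ex_center) / f$ex_width)^2), numeric(length(ex)))
  fl_names <- vapply(config$fluorophores, `[[`, "", "name")
  colnames(em_load) <- colnames(ex_load) <- fl_names

  class_idx <- match(meta$class[match(samples, meta$sample_id)], config$class_names)
  abund <- matrix(NA_real_, length(samples), n_f, dimnames = list(samples, fl_names))
  for (j in seq_len(n_f)) {
    f <- config$fluorophores[[j]]
    mu <- f$mean_abundance[class_idx]
    if (f$sdlog > 0 && any(mu > 0)) {
      a <- numeric(length(samples))
      pos <- mu > 0
      a[pos] <- exp(stats::rnorm(sum(pos), log(mu[pos]), f$sdlog))
      abund[, j] <- a
    } else abund[, j] <- mu
  }

  # scatter ridge profiles shared across samples (unit amplitude); ridge
  # widths follow the monochromator bandpass (5 nm slits), well inside the
  # default removal bands
  ridge <- matrix(0, length(em), length(ex))
  raman_em <- function(lx) 1 / (1 / lx - config$raman_shift_cm1 * 1e-7)
  for (j in seq_along(ex)) {
    ridge[, j] <- config$scatter$rayleigh1 * exp(-0.5 * ((em - ex[j]) / 3)^2) +
      config$scatter$rayleigh2 * exp(-0.5 * ((em - 2 * ex[j]) / 5)^2) +
      config$scatter$raman * exp(-0.5 * ((em - raman_em(ex[j])) / 4)^2)
  }

  n_meas <- nrow(meta)
  data <- array(0, dim = c(n_meas, length(em), length(ex)))
  scores <- matrix(NA_real_, n_meas, n_f,
                   dimnames = list(meta$measurement_id, fl_names))
  clean_max <- 0
  for (k in seq_len(n_meas)) {
    a <- abund[match(meta$sample_id[k], samples), ]
    slab <- em_load %*% (t(ex_load) * a)   # em x ex trilinear sum
    clean_max <- max(clean_max, max(slab))
    data[k, , ] <- slab
    scores[k, ] <- a
  }
  if (clean_max == 0) clean_max <- 1
  # additive detector noise is not clipped: blank-subtracted EEMs carry
  # small negative excursions in signal-free regions
  for (k in seq_len(n_meas)) {
    slab <- data[k, , ] + clean_max * ridge
    if (config$noise_sd > 0)
      slab <- slab + stats::rnorm(length(slab), 0, config$noise_sd * clean_max)
    data[k, , ] <- slab
  }
  cube <- eem_cube(data, em, ex, sample_ids = meta$measurement_id)
  list(cube = cube, metadata = meta,
       true_factors = list(scores = scores, em_loadings = em_load,
                           ex_loadings = ex_load))
}

#' Rewrite a synthetic config's class effects into a named contrast pattern
#'
#' Places the three-class contrast in one block, the other, or splits it
#' between them. `"complementary"` gives each block only part of the
#' target-vs-rest signal: the NMR metabolite means separate the target
#' (class 1) from class 2 but not class 3, while the fluorophore abundances
#' separate it from class 3 but not class 2. `"block1_only"` /
#' `"block2_only"` put the full contrast in one block and flatten the other;
#' `"both"` duplicates it; `"custom"` leaves the config untouched.
#'
#' @param config A [synthetic_config()] with 3 classes.
#' @param contrast Pattern name.
#' @return The modified `synthetic_config`.
#' @export
contrast_config <- function(config,
                            contrast = c("complementary", "block1_only",
                                         "block2_only", "both", "custom")) {
  stopifnot(inherits(config, "synthetic_config"))
  contrast <- match.arg(contrast)
  if (contrast == "custom") return(config)
  if (config$n_classes != 3) fail("built-in contrast patterns require 3 classes")
  flat <- function(x) rep(log(x), 3)
  nmr_eff <- switch(contrast,
    complementary = list(oleuropein = log(c(3.0, 1.2, 3.0)),
                         mannitol   = log(c(3.0, 6.0, 3.0))),
    block1_only   = list(oleuropein = log(c(3.0, 1.2, 1.2)),
                         mannitol   = log(c(3.0, 6.0, 6.0))),
    block2_only   = list(oleuropein = flat(2.0), mannitol = flat(4.5)),
    both          = list(oleuropein = log(c(3.0, 1.2, 1.2)),
                         mannitol   = log(c(3.0, 6.0, 6.0))))
  eem_eff <- switch(contrast,
    complementary = list(chlorogenic_acid   = c(5.0, 5.0, 1.8),
                         phenolic_compounds = c(3.0, 3.0, 1.2)),
    block1_only   = list(chlorogenic_acid   = c(4.0, 4.0, 4.0),
                         phenolic_compounds = c(2.5, 2.5, 2.5)),
    block2_only   = list(chlorogenic_acid   = c(5.0, 1.8, 1.8),
                         phenolic_compounds = c(3.0, 1.2, 1.2)),
    both          = list(chlorogenic_acid   = c(5.0, 1.8, 1.8),
                         phenolic_compounds = c(3.0, 1.2, 1.2)))
  config$metabolites <- lapply(config$metabolites, function(m) {
    m$class_log_mean <- if (m$name %in% names(nmr_eff)) nmr_eff[[m$name]]
                        else rep(mean(m$class_log_mean), 3)
    m
  })
  config$fluorophores <- lapply(config$fluorophores, function(f) {
    f$mean_abundance <- if (f$name %in% names(eem_eff)) eem_eff[[f$name]]
                        else rep(mean(f$mean_abundance), 3)
    f
  })
  config
}

#' Generate a paired two-block (NMR + EEM) dataset with known class structure
#'
#' Produces a bucketed, total-intensity-normalized NMR block and a
#' scatter-cleaned, variance-normalized, unfolded EEM block over the *same*
#' measurement set, with the class contrast placed in one block, the other,
#' or split between them — so the benefit of fusing the blocks is testable
#' against ground truth. `contrast = "complementary"` gives each block only
#' part of the target-vs-rest signal (block 1 cannot separate the target
#' from class 3, block 2 cannot separate it from class 2), the situation in
#' which mid-level fusion should beat either single block.
#'
#' @param config A [synthetic_config()] (its libraries are overridden by the
#'   contrast pattern below unless `contrast = "custom"`).
#' @param contrast One of `"complementary"`, `"block1_only"`,
#'   `"block2_only"`, `"both"`, `"custom"` (use config libraries as given).
#' @param bucket_args,scatter_args Optional argument lists passed on to
#'   [bucket()] and [remove_scatter()].
#' @return A list with `nmr` (normalized bucket table), `eem` (unfolded
#'   matrix), `eem_cube` (preprocessed cube), `metadata`, `truth` (per-block
#'   Fisher ratios of the class structure and the generating libraries).
#' @export
generate_fusion_dataset <- function(config,
                                    contrast = c("complementary", "block1_only",
                                                 "block2_only", "both", "custom"),
                                    bucket_args = list(), scatter_args = list()) {
  stopifnot(inherits(config, "synthetic_config"))
  contrast <- match.arg(contrast)
  config <- contrast_config(config, contrast)

  nmr_gen <- generate_nmr(config)
  eem_gen <- generate_eem(config)
  if (!identical(nmr_gen$metadata$measurement_id, eem_gen$metadata$measurement_id))
    fail("sample sets of the two blocks do not match")  # defensive; shared design

  bt <- do.call(bucket, c(list(nmr_gen$spectra), bucket_args))
  bt <- normalize_total(bt)

  cube <- do.call(remove_scatter, c(list(eem_gen$cube), scatter_args))
  cube <- interpolate_missing(cube)
  cube <- normalize_sample_variance(cube)
  X2 <- unfold(cube)

  fisher <- function(X, cls) {
    mu <- colMeans(X)
    B <- 0; W <- 0
    for (g in unique(cls)) {
      Xg <- X[cls == g, , drop = FALSE]
      B <- B + nrow(Xg) * sum((colMeans(Xg) - mu)^2)
      W <- W + sum(sweep(Xg, 2, colMeans(Xg))^2)
    }
    B / W
  }
  cls <- nmr_gen$metadata$class
  list(nmr = bt, eem = X2, eem_cube = cube, metadata = nmr_gen$metadata,
       truth = list(fisher_nmr = fisher(bt$matrix, cls),
                    fisher_eem = fisher(X2, cls),
                    true_concentrations = nmr_gen$true_concentrations,
                    true_factors = eem_gen$true_factors,
                    contrast = contrast))
}
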