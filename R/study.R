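#' Configure an end-to-end two-block authentication study
#'
#' Bundles every stage's settings: the synthetic design (or paths to user
#' data), the target class for one-class modeling, bucketing and scatter
#' settings, the PARAFAC scan, SIMCA and ComDim options, the duplex split
#' ratio and the master seed. Validated up front; serialized into the run
#' report for provenance.
#'
#' @param synthetic A [synthetic_config()].
#' @param contrast Class-contrast pattern for [generate_fusion_dataset()].
#' @param target_class Label of the modeled (target) class.
#' @param bucket_args Arguments for [bucket()] (width, range, exclusions).
#' @param scatter_args Arguments for [remove_scatter()].
#' @param parafac_range Candidate component numbers for the PARAFAC scan.
#' @param parafac_starts Initializations per PARAFAC fit in the study scan
#'   (the stand-alone [fit_parafac()] default is 10; the driver uses fewer
#'   because the scan is a diagnostic, not the final decomposition).
#' @param simca_A_range Candidate SIMCA component numbers.
#' @param n_cd `"auto"` (smallest cumulative explained variance >= 90%) or
#'   a fixed number of common dimensions.
#' @param split_ratio Duplex calibration fraction (default 0.8).
#' @param include_eem If `FALSE`, run the NMR-only path (fusion skipped).
#' @param run_parafac_scan If `FALSE`, skip the PARAFAC diagnostic stage.
#' @param rng_seed Master seed; fans out per stage via [stage_seed()].
#' @return An object of class `study_config`.
#' @export
study_config <- function(synthetic = synthetic_config(),
                         contrast = "complementary",
                         target_class = "chianti_siena",
                         bucket_args = list(),
                         scatter_args = list(),
                         parafac_range = 2:4,
                         parafac_starts = 3,
                         simca_A_range = 1:5,
                         n_cd = "auto",
                         split_ratio = 0.8,
                         include_eem = TRUE,
                         run_parafac_scan = TRUE,
                         rng_seed = 1L) {
  stopifnot(inherits(synthetic, "synthetic_config"))
  if (!identical(n_cd, "auto") && (!is.numeric(n_cd) || n_cd < 1))
    fail("n_cd must be 'auto' or a positive integer")
  if (split_ratio <= 0 || split_ratio >= 1) fail("split_ratio must be in (0, 1)")
  if (!target_class %in% synthetic$class_names)
    fail("target_class '%s' is not one of: %s", target_class,
         paste(synthetic$class_names, collapse = ", "))
  structure(list(synthetic = synthetic, contrast = contrast,
                 target_class = target_class,
                 bucket_args = bucket_args, scatter_args = scatter_args,
                 parafac_range = parafac_range, parafac_starts = parafac_starts,
                 simca_A_range = simca_A_range, n_cd = n_cd,
                 split_ratio = split_ratio, include_eem = include_eem,
                 run_parafac_scan = run_parafac_scan,
                 rng_seed = as.integer(rng_seed)),
            class = "study_config")
}

# leave-one-sample-out reduced distances of target calibration rows:
# replicates of a physical sample leave together, so the tuned threshold is
# not inflated by replicate leakage
loo_target_distances <- function(X, groups, A) {
  d <- numeric(nrow(X))
  for (g in unique(groups)) {
    out <- groups == g
    m <- fit_simca(X[!out, , drop = FALSE], min(A, sum(!out) - 2))
    d[out] <- reduced_distance(m, X[out, , drop = FALSE])
  }
  d
}

# fit, tune and evaluate a single-block SIMCA for the target class
run_block_simca <- function(X, meta, split, target_class, A_range, block_name) {
  cal <- split$calibration; test <- split$test
  is_t <- meta$class == target_class
  Xcal_t <- X[intersect(cal, which(is_t)), , drop = FALSE]
  groups_t <- meta$sample_id[intersect(cal, which(is_t))]
  A_range <- A_range[A_range <= nrow(Xcal_t) - 2]
  if (!length(A_range)) fail("too few target calibration samples for SIMCA in block %s", block_name)
  sel <- select_n_components(Xcal_t, A_range)
  model <- fit_simca(Xcal_t, sel$chosen, target_label = target_class)
  d_t <- loo_target_distances(Xcal_t, groups_t, sel$chosen)
  d_nt <- reduced_distance(model, X[setdiff(cal, which(is_t)), , drop = FALSE])
  model$threshold <- as.numeric(optimize_threshold(d_t, d_nt))
  train <- evaluate(model, X[cal, , drop = FALSE], is_t[cal])
  testm <- evaluate(model, X[test, , drop = FALSE], is_t[test])
  expl <- 100 * sum(model$eigenvalues[seq_len(model$A)]) / sum(model$eigenvalues)
  list(model = model, A = sel$chosen, component_selection = sel$diagnostics,
       train = train, test = testm, explained_variance = expl,
       block = block_name)
}

metrics_row <- function(m, model_name, set_name) {
  data.frame(model = model_name, set = set_name,
             accuracy = m$accuracy, sensitivity = m$sensitivity,
             specificity = m$specificity,
             TP = m$TP, FN = m$FN, TN = m$TN, FP = m$FP)
}

#' Run the full two-block authentication study
#'
#' Executes the study workflow end to end on synthetic data: simulate the
#' paired blocks, preprocess (bucketing + total-intensity normalization;
#' scatter removal + interpolation + unit-variance normalization +
#' unfolding), run the PARAFAC rank scan on the preprocessed cube, split
#' calibration/test by a class-stratified duplex on the joined normalized
#' blocks (replicates never straddle the split), fit and tune a one-class
#' SIMCA per block, fit the ComDim fusion model and the multiblock SD/OD
#' one-class classifier, and assemble the per-model train/test metrics
#' table. Fully deterministic for a fixed config (including seed).
#'
#' @param config A [study_config()].
#' @return An object of class `run_report`: `metrics` (one row per model
#'   and set), `parafac`, `comdim` (explained variance, saliences), models,
#'   split, metadata and the serialized config.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  syn <- config$synthetic
  syn$rng_seed <- stage_seed(config$rng_seed, "simulate")

  ds <- generate_fusion_dataset(syn, config$contrast,
                                bucket_args = config$bucket_args,
                                scatter_args = config$scatter_args)
  meta <- ds$metadata
  target <- config$target_class
  if (!any(meta$class == target)) fail("no samples of target class '%s'", target)

  # PARAFAC diagnostics on the preprocessed cube
  parafac_res <- NULL
  if (config$run_parafac_scan && config$include_eem) {
    parafac_res <- select_components(ds$eem_cube, config$parafac_range,
                                     n_starts = config$parafac_starts,
                                     seed = stage_seed(config$rng_seed, "parafac"))
    parafac_res$models <- NULL  # keep the report light; diagnostics retained
  }

  # class-stratified duplex split on the joined normalized blocks
  blocks_all <- list(nmr = ds$nmr$matrix)
  if (config$include_eem) blocks_all$eem <- ds$eem
  nb_all <- normalize_blocks(blocks_all)
  joined <- do.call(cbind, lapply(nb_all, `[[`, "matrix"))
  cal <- integer(0); test <- integer(0)
  for (cl in unique(meta$class)) {
    rows <- which(meta$class == cl)
    sp <- duplex_split(joined[rows, , drop = FALSE], ratio = config$split_ratio,
                       groups = meta$sample_id[rows])
    cal <- c(cal, rows[sp$calibration]); test <- c(test, rows[sp$test])
  }
  split <- list(calibration = sort(cal), test = sort(test))

  simca_nmr <- run_block_simca(ds$nmr$matrix, meta, split, target,
                               config$simca_A_range, "nmr")
  simca_eem <- NULL
  if (config$include_eem)
    simca_eem <- run_block_simca(ds$eem, meta, split, target,
                                 config$simca_A_range, "eem")

  comdim_res <- NULL; occ <- NULL; occ_train <- NULL; occ_test <- NULL
  notices <- character(0)
  if (config$include_eem) {
    cal_t <- intersect(split$calibration, which(meta$class == target))
    blocks_t <- list(nmr = ds$nmr$matrix[cal_t, , drop = FALSE],
                     eem = ds$eem[cal_t, , drop = FALSE])
    n_cd <- config$n_cd
    if (identical(n_cd, "auto")) {
      probe <- fit_comdim(
        normalize_blocks(lapply(blocks_t, function(X) sweep(X, 2, colMeans(X)))),
        n_cd = min(8, length(cal_t) - 1))
      cum <- cumsum(probe$explained_variance)
      n_cd <- if (any(cum >= 90)) min(which(cum >= 90)) else length(cum)
    }
    occ <- fit_mb_occ(blocks_t, n_cd = n_cd, target_label = target)
    cal_blocks <- list(nmr = ds$nmr$matrix[split$calibration, , drop = FALSE],
                       eem = ds$eem[split$calibration, , drop = FALSE])
    is_t <- meta$class == target
    # target distances by leave-one-sample-out (replicates leave together),
    # mirroring the single-block threshold tuning
    groups_t <- meta$sample_id[cal_t]
    d_t <- numeric(length(cal_t))
    for (g in unique(groups_t)) {
      out <- groups_t == g
      occ_g <- fit_mb_occ(lapply(blocks_t, function(X) X[!out, , drop = FALSE]),
                          n_cd = min(n_cd, sum(!out) - 1), target_label = target)
      d_t[out] <- predict(occ_g, lapply(blocks_t, function(X) X[out, , drop = FALSE]))$distance
    }
    d_nt <- predict(occ, lapply(list(nmr = ds$nmr$matrix, eem = ds$eem), function(X)
      X[setdiff(split$calibration, cal_t), , drop = FALSE]))$distance
    occ$threshold <- as.numeric(optimize_threshold(d_t, d_nt))
    occ_train <- evaluate(occ, cal_blocks, is_t[split$calibration])
    occ_test <- evaluate(occ, list(nmr = ds$nmr$matrix[split$test, , drop = FALSE],
                                   eem = ds$eem[split$test, , drop = FALSE]),
                         is_t[split$test])
    # exploratory ComDim on all calibration samples (mean-centered blocks)
    comdim_res <- fit_comdim(
      normalize_blocks(lapply(cal_blocks, function(X) sweep(X, 2, colMeans(X)))),
      n_cd = n_cd)
  } else {
    notices <- c(notices, "EEM block omitted: fusion stages skipped")
  }

  metrics <- rbind(
    metrics_row(simca_nmr$train, "nmr_simca", "train"),
    metrics_row(simca_nmr$test, "nmr_simca", "test"),
    if (!is.null(simca_eem)) metrics_row(simca_eem$train, "eem_simca", "train"),
    if (!is.null(simca_eem)) metrics_row(simca_eem$test, "eem_simca", "test"),
    if (!is.null(occ_train)) metrics_row(occ_train, "mb_occ", "train"),
    if (!is.null(occ_test)) metrics_row(occ_test, "mb_occ", "test"))

  structure(list(
    metrics = metrics,
    parafac = if (!is.null(parafac_res))
      list(chosen = parafac_res$chosen, diagnostics = parafac_res$diagnostics,
           low_variance = parafac_res$low_variance),
    comdim = if (!is.null(comdim_res))
      list(explained_variance = explained_variance(comdim_res),
           saliences = comdim_res$saliences, n_cd = comdim_res$n_cd),
    models = list(nmr_simca = simca_nmr, eem_simca = simca_eem, mb_occ = occ),
    split = split, metadata = meta, truth = ds$truth,
    notices = notices,
    config = config, seed = config$rng_seed
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed", x$seed, ")\n")
  if (length(x$notices)) cat(paste0("  NOTE: ", x$notices, "\n"))
  if (!is.null(x$parafac))
    cat(sprintf("  PARAFAC scan: chose F = %d\n", x$parafac$chosen))
  if (!is.null(x$comdim))
    cat(sprintf("  ComDim: %d CDs, cumulative variance %.1f%%\n",
                x$comdim$n_cd, max(x$comdim$explained_variance$cumulative)))
  cat("  classification metrics (%):\n")
  print(x$metrics[, c("model", "set", "accuracy", "sensitivity", "specificity")],
        row.names = FALSE)
  invisible(x)
}

#' Write a run report's tables to a directory
#'
#' Writes the metrics table, PARAFAC diagnostics, ComDim variance/salience
#' tables and the serialized configuration as delimited text / YAML.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$metrics, file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$parafac))
    utils::write.table(report$parafac$diagnostics,
                       file.path(dir, "parafac_diagnostics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$comdim)) {
    utils::write.table(report$comdim$explained_variance,
                       file.path(dir, "comdim_variance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(block = rownames(report$comdim$saliences),
                                  report$comdim$saliences),
                       file.path(dir, "comdim_saliences.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- report$config
  yaml::write_yaml(list(
    target_class = cfg$target_class, contrast = cfg$contrast,
    split_ratio = cfg$split_ratio, n_cd = cfg$n_cd,
    rng_seed = cfg$rng_seed,
    design = list(n_classes = cfg$synthetic$n_classes,
                  n_samples_per_class = cfg$synthetic$n_samples_per_class,
                  n_replicates = cfg$synthetic$n_replicates,
                  noise_sd = cfg$synthetic$noise_sd)),
    file.path(dir, "config.yaml"))
  invisible(dir)
}
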