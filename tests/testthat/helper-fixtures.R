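# Small designs for unit tests; the acceptance suite uses the full-size
# study conditions.

tiny_nmr_config <- function(...) {
  args <- utils::modifyList(
    list(n_samples_per_class = 4, n_replicates = 2,
         ppm_res = 0.01, noise_sd = 0.002, rng_seed = 42L),
    list(...))
  do.call(synthetic_config, args)
}

# coarse emission grid keeps PARAFAC unit tests fast
tiny_eem_config <- function(...) {
  args <- utils::modifyList(
    list(n_samples_per_class = 5, n_replicates = 1,
         em_axis = seq(250, 530, by = 5), noise_sd = 0.01, rng_seed = 42L),
    list(...))
  do.call(synthetic_config, args)
}

no_scatter <- list(rayleigh1 = 0, rayleigh2 = 0, raman = 0)

# hand-built bucket table for arithmetic checks
toy_bucket_table <- function(mat, width = 0.04) {
  centers <- 0.52 + width * (seq_len(ncol(mat)) - 1)
  structure(list(
    matrix = `dimnames<-`(mat, list(paste0("S", seq_len(nrow(mat))),
                                    sprintf("%.3f", centers))),
    bucket_edges = data.frame(lower = centers - width / 2,
                              upper = centers + width / 2, center = centers),
    excluded_regions = list(), row_ids = paste0("S", seq_len(nrow(mat))),
    row_total_full = rowSums(mat),
    sample_id = paste0("S", seq_len(nrow(mat))),
    replicate_id = rep(1L, nrow(mat)), normalized = FALSE
  ), class = "bucket_table")
}

# multivariate normal target-class data with decaying latent spectrum
gauss_class <- function(n, p = 20, rank = p, sd_decay = 0.7, seed = 1) {
  set.seed(seed)
  sds <- sd_decay^(seq_len(rank) - 1)
  scores <- matrix(rnorm(n * rank), n) %*% diag(sds, rank)
  rot <- qr.Q(qr(matrix(rnorm(p * rank), p)))[, seq_len(rank), drop = FALSE]
  scores %*% t(rot)
}
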