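#!/usr/bin/env Rscript
# Stage 5 — single-block one-class SIMCA for the Chianti-Siena class.
#
# Splits calibration/test by a class-stratified duplex on the joined
# normalized blocks (replicate triplicates never straddle the split), picks
# the component count per block by leave-one-out RMSECV, tunes the reduced
# distance threshold to maximize sensitivity + specificity, and reports
# train/test metrics per block.

library(chemfuse)

meta <- read_metadata("scratch/data/metadata.tsv")
bt <- read_bucket_table("scratch/data/nmr_buckets.tsv")
eem_df <- utils::read.delim("scratch/data/eem_unfolded.tsv", check.names = FALSE)
eem <- as.matrix(eem_df[, -1]); rownames(eem) <- eem_df[[1]]
target <- "chianti_siena"

# stratified duplex split, shared with the fusion stage
nb <- normalize_blocks(list(nmr = bt$matrix, eem = eem))
joined <- cbind(nb$nmr$matrix, nb$eem$matrix)
cal <- integer(0); test <- integer(0)
for (cl in unique(meta$class)) {
  rows <- which(meta$class == cl)
  sp <- duplex_split(joined[rows, , drop = FALSE], 0.8, groups = meta$sample_id[rows])
  cal <- c(cal, rows[sp$calibration]); test <- c(test, rows[sp$test])
}
split <- data.frame(measurement_id = meta$measurement_id,
                    set = ifelse(seq_len(nrow(meta)) %in% cal, "calibration", "test"))
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
utils::write.table(split, "results/tables/split.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

fit_block <- function(X, name) {
  is_t <- meta$class == target
  rows_t <- intersect(cal, which(is_t))
  Xt <- X[rows_t, , drop = FALSE]
  sel <- select_n_components(Xt, 1:min(5, nrow(Xt) - 2))
  model <- fit_simca(Xt, sel$chosen, target_label = target)
  # threshold from leave-one-sample-out target distances vs calibration others
  d_t <- numeric(nrow(Xt)); grp <- meta$sample_id[rows_t]
  for (g in unique(grp)) {
    out <- grp == g
    mg <- fit_simca(Xt[!out, , drop = FALSE], min(sel$chosen, sum(!out) - 2))
    d_t[out] <- reduced_distance(mg, Xt[out, , drop = FALSE])
  }
  d_nt <- reduced_distance(model, X[setdiff(cal, rows_t), , drop = FALSE])
  model$threshold <- as.numeric(optimize_threshold(d_t, d_nt))
  rbind(
    data.frame(model = name, set = "train", A = sel$chosen,
               unclass(evaluate(model, X[cal, , drop = FALSE], is_t[cal]))),
    data.frame(model = name, set = "test", A = sel$chosen,
               unclass(evaluate(model, X[test, , drop = FALSE], is_t[test]))))
}

metrics <- rbind(fit_block(bt$matrix, "nmr_simca"), fit_block(eem, "eem_simca"))
utils::write.table(metrics, "results/tables/simca_metrics.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("single-block SIMCA for", target, "(metrics in %):\n")
print(metrics[, c("model", "set", "A", "accuracy", "sensitivity", "specificity")],
      row.names = FALSE)
cat("wrote results/tables/{split,simca_metrics}.tsv\n")
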