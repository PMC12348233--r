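#!/usr/bin/env Rscript
# Stage 4 — PARAFAC rank scan on the cleaned cube.
#
# Fits non-negative trilinear models for F = 2..4, tabulates CORCONDIA and
# explained variance, and exports the loadings of the chosen model. The
# fluorophore identities behind the components can be read off the
# excitation/emission maxima of the loadings.

library(chemfuse)

cube <- read_eem_cube("scratch/data/eem_clean")
scan <- select_components(cube, 2:4, n_starts = 3, seed = stage_seed(1L, "parafac"))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
utils::write.table(scan$diagnostics, "results/tables/parafac_scan.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

best <- scan$models[[as.character(scan$chosen)]]
for (part in c("em_loadings", "ex_loadings", "scores"))
  utils::write.table(best[[part]], file.path("results/tables",
                                             paste0("parafac_", part, ".tsv")),
                     sep = "\t", quote = FALSE)

cat("rank scan:\n"); print(scan$diagnostics, row.names = FALSE)
cat(sprintf("chose F = %d (largest F with CORCONDIA >= 80)\n", scan$chosen))
maxima <- data.frame(
  component = colnames(best$em_loadings),
  em_max_nm = cube$em_axis[apply(best$em_loadings, 2, which.max)],
  ex_max_nm = cube$ex_axis[apply(best$ex_loadings, 2, which.max)])
print(maxima, row.names = FALSE)
cat("wrote results/tables/parafac_*.tsv\n")
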