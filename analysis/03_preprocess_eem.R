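#!/usr/bin/env Rscript
# Stage 3 — EEM scatter handling and normalization.
#
# Masks first/second-order Rayleigh and Raman scatter, fills the masked
# bands by shape-preserving interpolation along the emission mode, zeroes
# the physically meaningless region below the first-order Rayleigh line,
# normalizes every sample slab to unit variance and unfolds the cube into a
# samples x (emission.excitation) matrix for classification.

library(chemfuse)

cube <- read_eem_cube("scratch/data/eem_raw")
masked <- remove_scatter(cube)
cat(sprintf("masked %.1f%% of cube values as scatter\n", 100 * mean(masked$mask)))

cleaned <- normalize_sample_variance(interpolate_missing(masked))
write_eem_cube(cleaned, "scratch/data/eem_clean")

U <- unfold(cleaned)
utils::write.table(data.frame(measurement_id = rownames(U), U, check.names = FALSE),
                   "scratch/data/eem_unfolded.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("unfolded cube: %d samples x %d wavelength pairs\n", nrow(U), ncol(U)))
cat("wrote scratch/data/{eem_clean,eem_unfolded.tsv}\n")
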