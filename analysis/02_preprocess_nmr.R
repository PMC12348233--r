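#!/usr/bin/env Rscript
# Stage 2 — NMR bucketing.
#
# Integrates each spectrum into 0.04 ppm buckets over 0.50-10.00 ppm,
# drops every bucket touching the residual water (4.50-5.20 ppm) and
# methanol (3.28-3.40 ppm) regions, and normalizes each row to total
# intensity. Writes the normalized bucket table.

library(chemfuse)

meta <- read_metadata("scratch/data/metadata.tsv")
spectra <- lapply(meta$measurement_id, function(id)
  read_spectrum(file.path("scratch/data/spectra", paste0(id, ".tsv")),
                sample_id = meta$sample_id[meta$measurement_id == id],
                replicate_id = meta$replicate_id[meta$measurement_id == id]))

bt <- normalize_total(bucket(spectra))
write_bucket_table(bt, "scratch/data/nmr_buckets.tsv")

cat(sprintf("bucketed %d spectra into %d retained buckets (max |row sum - 1| = %.1e)\n",
            nrow(bt$matrix), ncol(bt$matrix), max(abs(rowSums(bt$matrix) - 1))))
cat("wrote scratch/data/nmr_buckets.tsv\n")
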