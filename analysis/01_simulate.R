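#!/usr/bin/env Rscript
# Stage 1 — simulate the two-block study.
#
# Emulates the field design: three Tuscan subregions (Chianti-Siena,
# Grosseto, Val d'Orcia), 10 orchards per subregion, every extract measured
# in triplicate by both 1H NMR and EEM fluorescence. The class contrast is
# "complementary": the NMR block cannot separate the target subregion from
# Val d'Orcia, the EEM block cannot separate it from Grosseto — the setting
# in which data fusion has something to add. Writes raw spectra, the raw EEM
# cube and the sample metadata under scratch/data/.

library(chemfuse)

seed <- 1L
cfg <- contrast_config(synthetic_config(rng_seed = stage_seed(seed, "simulate")),
                       "complementary")

nmr <- generate_nmr(cfg)
eem <- generate_eem(cfg)

dir.create("scratch/data/spectra", showWarnings = FALSE, recursive = TRUE)
for (id in names(nmr$spectra))
  write_spectrum(nmr$spectra[[id]], file.path("scratch/data/spectra", paste0(id, ".tsv")))
write_eem_cube(eem$cube, "scratch/data/eem_raw")
write_metadata(nmr$metadata, "scratch/data/metadata.tsv")

cat(sprintf("simulated %d measurements (%d samples x %d replicates, %d classes)\n",
            nrow(nmr$metadata), cfg$n_samples_per_class * cfg$n_classes,
            cfg$n_replicates, cfg$n_classes))
cat(sprintf("NMR: %d points / spectrum; EEM: %d emission x %d excitation\n",
            length(cfg$ppm), length(cfg$em_axis), length(cfg$ex_axis)))
cat("wrote scratch/data/{spectra,eem_raw,metadata.tsv}\n")
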