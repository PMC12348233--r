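test_that("spectrum files round-trip bitwise and reject malformed input", {
  gen <- generate_nmr(tiny_nmr_config())
  s <- gen$spectra[[1]]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(s, f)
  s2 <- read_spectrum(f, s$sample_id, s$replicate_id)
  expect_identical(s2$ppm, s$ppm)
  expect_identical(s2$intensity, s$intensity)
  # decimal commas are rejected, not misparsed
  writeLines(c("ppm\tintensity", "1,5\t2.0"), f)
  expect_error(read_spectrum(f), "decimal comma")
  # first bad line is named
  writeLines(c("ppm\tintensity", "1.0\t2.0", "oops\t3.0"), f)
  expect_error(read_spectrum(f), "line 3")
})

test_that("bucket tables round-trip bitwise", {
  gen <- generate_nmr(tiny_nmr_config())
  bt <- normalize_total(bucket(gen$spectra[1:4]))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_bucket_table(bt, f)
  bt2 <- read_bucket_table(f)
  expect_identical(bt2$matrix, bt$matrix)
  expect_equal(bt2$bucket_edges$center, bt$bucket_edges$center)
  expect_identical(bt2$row_total_full, unname(bt$row_total_full))
  expect_identical(bt2$normalized, TRUE)
})

test_that("EEM cubes round-trip through a directory with masks intact", {
  gen <- generate_eem(tiny_eem_config(n_samples_per_class = 2))
  cube <- remove_scatter(gen$cube, below_rayleigh = "keep")
  d <- withr::local_tempdir()
  write_eem_cube(cube, d)
  cube2 <- read_eem_cube(d)
  expect_identical(cube2$mask, cube$mask)
  expect_identical(cube2$data[!cube2$mask], cube$data[!cube$mask])
  expect_identical(cube2$em_axis, cube$em_axis)
  # a missing per-sample file is reported by name
  unlink(file.path(d, list.files(d, pattern = "tsv$")[1]))
  expect_error(read_eem_cube(d), "expected EEM file")
  expect_error(read_eem_cube(withr::local_tempdir()), "manifest")
})

test_that("metadata tables round-trip and enforce their columns", {
  gen <- generate_nmr(tiny_nmr_config())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(gen$metadata, f)
  expect_identical(read_metadata(f), gen$metadata)
  writeLines("sample_id\tclass\n1\ta", f)
  expect_error(read_metadata(f), "measurement_id")
})

test_that("stage seeds are deterministic and independent across stages", {
  expect_identical(stage_seed(7, "simulate"), stage_seed(7, "simulate"))
  expect_false(stage_seed(7, "simulate") == stage_seed(7, "parafac"))
  expect_true(stage_seed(.Machine$integer.max, "x") < 2^31)
})

small_study <- function(seed = 3, ...) {
  study_config(
    synthetic = synthetic_config(n_samples_per_class = 7, n_replicates = 2,
                                 ppm_res = 0.01,
                                 em_axis = seq(250, 530, by = 5)),
    parafac_range = 2:3, parafac_starts = 2, simca_A_range = 1:3,
    rng_seed = seed, ...)
}

test_that("the study driver runs end to end and is bitwise reproducible", {
  r1 <- run_study(small_study())
  r2 <- run_study(small_study())
  expect_identical(r1, r2)
  expect_setequal(unique(r1$metrics$model), c("nmr_simca", "eem_simca", "mb_occ"))
  expect_true(all(r1$metrics$accuracy >= 0 & r1$metrics$accuracy <= 100, na.rm = TRUE))
  # every measurement lands on exactly one side of the split
  expect_equal(sort(c(r1$split$calibration, r1$split$test)),
               seq_len(nrow(r1$metadata)))
  d <- withr::local_tempdir()
  write_run_report(r1, d)
  expect_true(all(file.exists(file.path(d, c("metrics.tsv", "config.yaml")))))
})

test_that("omitting the EEM block degrades gracefully to the single-block path", {
  r <- run_study(small_study(include_eem = FALSE, run_parafac_scan = FALSE))
  expect_setequal(unique(r$metrics$model), "nmr_simca")
  expect_match(r$notices, "fusion stages skipped")
  expect_null(r$comdim)
})
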