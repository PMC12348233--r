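test_that("default metabolite library carries the secoiridoid and sugar marker shifts", {
  lib <- default_metabolite_library()
  nm <- vapply(lib, `[[`, "", "name")
  oleu <- lib[[which(nm == "oleuropein")]]
  expect_setequal(vapply(oleu$peaks, `[[`, 0, "center"), c(1.64, 2.80, 3.71, 6.73))
  mann <- lib[[which(nm == "mannitol")]]
  expect_setequal(vapply(mann$peaks, `[[`, 0, "center"), c(3.65, 3.81))
  gluc <- lib[[which(nm == "glucose")]]
  expect_setequal(vapply(gluc$peaks, `[[`, 0, "center"), c(3.37, 4.53))
  # solvent residuals sit inside the standard exclusion windows
  water <- lib[[which(nm == "water_residual")]]$peaks[[1]]$center
  meoh <- lib[[which(nm == "methanol_residual")]]$peaks[[1]]$center
  expect_true(water > 4.50 && water < 5.20)
  expect_true(meoh > 3.28 && meoh < 3.40)
})

test_that("replicates and samples collapse to identical spectra when all variability is off", {
  lib <- lapply(default_metabolite_library(), function(m) { m$sdlog <- 0; m })
  cfg <- synthetic_config(n_samples_per_class = 3, n_replicates = 2,
                          metabolites = lib, ppm_res = 0.01, noise_sd = 0)
  gen <- generate_nmr(cfg)
  cls1 <- gen$metadata$measurement_id[gen$metadata$class == "chianti_siena"]
  ref <- gen$spectra[[cls1[1]]]$intensity
  for (id in cls1[-1])
    expect_identical(gen$spectra[[id]]$intensity, ref)
})

test_that("a single unit-area Lorentzian integrates to its concentration", {
  lib <- list(metabolite_spec("probe", list(peak_spec(5.25, 0.01, 1.0)),
                              class_log_mean = log(2.5), sdlog = 0))
  cfg <- synthetic_config(n_classes = 1, n_samples_per_class = 1, n_replicates = 1,
                          metabolites = lib,
                          fluorophores = default_fluorophore_library("leaf", 1),
                          ppm_res = 0.002, noise_sd = 0)
  gen <- generate_nmr(cfg)
  s <- gen$spectra[[1]]
  area <- sum(diff(s$ppm) * (s$intensity[-1] + s$intensity[-length(s$intensity)]) / 2)
  conc <- gen$true_concentrations[1, "probe"]
  expect_equal(conc, 2.5)
  # quadrature oracle at 10x resolution on the analytic lineshape
  xf <- seq(0, 10.5, by = 2e-4)
  yf <- conc * (0.01 / pi) / ((xf - 5.25)^2 + 0.01^2)
  oracle <- sum(diff(xf) * (yf[-1] + yf[-length(yf)]) / 2)
  expect_lt(abs(area - oracle) / oracle, 1e-3)
  expect_lt(abs(area - conc) / conc, 0.005)
})

test_that("noise-free spectra are exact weighted sums of the metabolite templates", {
  cfg <- tiny_nmr_config(noise_sd = 0)
  gen <- generate_nmr(cfg)
  ppm <- cfg$ppm
  templates <- vapply(cfg$metabolites, function(m) {
    tpl <- numeric(length(ppm))
    for (p in m$peaks)
      tpl <- tpl + p$relative_area * (p$width / pi) / ((ppm - p$center)^2 + p$width^2)
    tpl
  }, numeric(length(ppm)))
  for (k in c(1, 9, 24)) {
    sid <- gen$metadata$sample_id[k]
    expected <- as.vector(templates %*% gen$true_concentrations[sid, ])
    expect_lt(max(abs(gen$spectra[[k]]$intensity - expected)), 1e-12)
  }
})

test_that("generation is bit-reproducible for a fixed config", {
  cfg <- tiny_nmr_config()
  expect_identical(generate_nmr(cfg), generate_nmr(cfg))
})

test_that("a peak center outside the ppm axis is a configuration error", {
  lib <- list(metabolite_spec("bad", list(peak_spec(12.0)), class_log_mean = rep(0, 3)))
  expect_error(synthetic_config(metabolites = lib), "outside axis")
})
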