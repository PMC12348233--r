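flat_spectrum <- function(level = 1, res = 0.005) {
  ppm <- seq(0, 10.5, by = res)
  nmr_spectrum(ppm, rep(level, length(ppm)), "flat")
}

test_that("bucket edges enumerate the 0.50-10.00 ppm range and drop the partial tail", {
  bt <- bucket(flat_spectrum(), exclusions = list())
  # oracle: enumerate lower edges 0.50 + 0.04 k whose upper edge stays <= 10.00
  k <- Filter(function(kk) 0.50 + 0.04 * (kk + 1) <= 10.00 + 1e-9, 0:300)
  expect_equal(ncol(bt$matrix), length(k))
  expect_equal(ncol(bt$matrix), 237)
  expect_equal(bt$bucket_edges$lower, 0.50 + 0.04 * k)
  expect_lt(max(bt$bucket_edges$upper), 10.00 + 1e-12)
  # constant unit intensity: every bucket integrates to its width
  expect_equal(unname(bt$matrix[1, ]), rep(0.04, 237), tolerance = 1e-12)
})

test_that("default exclusions remove every bucket touching the solvent regions", {
  bt <- bucket(flat_spectrum())
  for (ex in list(c(4.50, 5.20), c(3.28, 3.40))) {
    overlap <- bt$bucket_edges$lower < ex[2] & bt$bucket_edges$upper > ex[1]
    expect_false(any(overlap))
  }
  # whole-bucket removal: 3.28-3.40 is not edge-aligned, so the flanking
  # buckets 3.26-3.30 and 3.38-3.42 must be gone too
  expect_false(any(abs(bt$bucket_edges$center - 3.28) < 0.021))
  expect_false(any(abs(bt$bucket_edges$center - 3.40) < 0.021))
})

test_that("retained bucket areas conserve the integral over the retained domain", {
  gen <- generate_nmr(tiny_nmr_config())
  s <- gen$spectra[[1]]
  bt <- bucket(s)
  # quadrature oracle over each retained interval at the native grid
  total_buckets <- sum(bt$matrix[1, ])
  oracle <- 0
  for (i in seq_len(nrow(bt$bucket_edges))) {
    lo <- bt$bucket_edges$lower[i]; up <- bt$bucket_edges$upper[i]
    xs <- c(lo, s$ppm[s$ppm > lo & s$ppm < up], up)
    ys <- approx(s$ppm, s$intensity, xout = xs)$y
    oracle <- oracle + sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
  }
  expect_lt(abs(total_buckets - oracle) / oracle, 1e-9)
})

test_that("total-intensity normalization follows the row-sum arithmetic and is idempotent", {
  bt <- toy_bucket_table(matrix(c(2, 2, 4), 1))
  nt <- normalize_total(bt)
  expect_equal(unname(nt$matrix[1, ]), c(0.25, 0.25, 0.5))
  expect_equal(normalize_total(nt)$matrix, nt$matrix)
  # synthetic tables: every row sums to one
  gen <- generate_nmr(tiny_nmr_config())
  nt2 <- normalize_total(bucket(gen$spectra))
  expect_lt(max(abs(rowSums(nt2$matrix) - 1)), 1e-10)
  # zero row total is an error naming the sample
  expect_error(normalize_total(toy_bucket_table(matrix(0, 1, 3))), "S1")
})

test_that("normalized profiles are invariant to spectrum scaling", {
  gen <- generate_nmr(tiny_nmr_config())
  s <- gen$spectra[[3]]
  s7 <- nmr_spectrum(s$ppm, 7 * s$intensity, s$sample_id, s$replicate_id)
  r1 <- normalize_total(bucket(s))$matrix
  r2 <- normalize_total(bucket(s7))$matrix
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("mean centering supports reference means for test-set projection", {
  X <- matrix(rnorm(60), 10)
  Xc <- mean_center(X)
  expect_lt(max(abs(colMeans(Xc))), 1e-12)
  expect_equal(unname(mean_center(X, attr(Xc, "means"))), unname(unclass(Xc)),
               ignore_attr = TRUE)
  # a test row equal to the training means centers to zero
  row <- matrix(attr(Xc, "means"), 1)
  expect_lt(max(abs(mean_center(row, attr(Xc, "means")))), 1e-12)
  expect_error(mean_center(X, 1:3), "length")
})

test_that("bucketing rejects spectra that do not cover the range", {
  ppm <- seq(2, 10.5, by = 0.01)
  s <- nmr_spectrum(ppm, rep(1, length(ppm)), "short")
  expect_error(bucket(s), "not covered")
  expect_error(nmr_spectrum(c(1, 2, 2), c(0, 0, 0)), "monotone")
})
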