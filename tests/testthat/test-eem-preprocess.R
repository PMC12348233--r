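toy_cube <- function(n = 2, em = seq(300, 320, 5), ex = c(280, 300), seed = 1) {
  set.seed(seed)
  eem_cube(array(runif(n * length(em) * length(ex)), c(n, length(em), length(ex))),
           em, ex)
}

test_that("blank subtraction is exact and grid-checked", {
  cube <- toy_cube()
  blank <- cube$data[1, , ]
  out <- subtract_blank(cube, blank)
  expect_lt(max(abs(out$data[1, , ])), 1e-15)
  expect_identical(subtract_blank(cube, matrix(0, 5, 2))$data, cube$data)
  offset <- matrix(0.25, 5, 2)
  shifted <- cube; shifted$data <- sweep(cube$data, c(2, 3), offset, "+")
  expect_lt(max(abs(subtract_blank(shifted, offset)$data - cube$data)), 1e-12)
  expect_error(subtract_blank(cube, matrix(0, 4, 2)), "emission")
})

test_that("scatter masking hits injected ridges and collapses at zero bandwidth", {
  em <- seq(250, 400, 2); ex <- seq(250, 400, 10)
  cube <- eem_cube(array(1, c(1, length(em), length(ex))), em, ex)
  out <- remove_scatter(cube, bandwidths = list(rayleigh1 = 10, raman = 0, rayleigh2 = 0),
                        below_rayleigh = "keep")
  for (j in seq_along(ex)) {
    on_ridge <- abs(em - ex[j]) <= 10
    expect_true(all(out$mask[1, on_ridge, j]))
  }
  out0 <- remove_scatter(cube, bandwidths = list(rayleigh1 = 0, raman = 0, rayleigh2 = 0),
                         below_rayleigh = "keep")
  expect_equal(sum(out0$mask), sum(outer(em, ex, "==")))
  # masking twice changes nothing further
  expect_identical(remove_scatter(out, bandwidths = list(rayleigh1 = 10, raman = 0, rayleigh2 = 0),
                                  below_rayleigh = "keep")$mask, out$mask)
})

test_that("interpolation restores linear segments, smooth profiles, and never negatives", {
  em <- seq(1, 5, 1)
  cube <- eem_cube(array(rep(c(1, 2, 3, 4, 5), 1), c(1, 5, 1)), em, 300)
  cube$data[1, 3, 1] <- NA; cube$mask[1, 3, 1] <- TRUE
  out <- interpolate_missing(cube)
  expect_equal(out$data[1, 3, 1], 3, tolerance = 1e-9)
  expect_false(any(out$mask))
  # identity when nothing is masked
  c2 <- toy_cube()
  expect_identical(interpolate_missing(c2)$data, c2$data)
  # Gaussian emission profile with a 5-point hole: error < 1% of peak
  em2 <- seq(250, 530, 2)
  prof <- exp(-0.5 * ((em2 - 420) / 30)^2)
  c3 <- eem_cube(array(prof, c(1, length(em2), 1)), em2, 300)
  hole <- 80:84
  c3$data[1, hole, 1] <- NA; c3$mask[1, hole, 1] <- TRUE
  out3 <- interpolate_missing(c3)
  expect_lt(max(abs(out3$data[1, hole, 1] - prof[hole])), 0.01)
  expect_true(all(out3$data >= 0))
  # a fully masked column is left missing and reported
  c4 <- toy_cube()
  c4$mask[1, , 1] <- TRUE; c4$data[1, , 1] <- NA
  expect_warning(out4 <- interpolate_missing(c4), "left missing")
  expect_true(all(is.na(out4$data[1, , 1])))
})

test_that("sample-mode variance normalization is scale-free and exact", {
  cube <- toy_cube(n = 3)
  cube$data[2, , ] <- 5 * cube$data[1, , ]  # scalar multiple pair
  out <- normalize_sample_variance(cube)
  for (i in 1:3) expect_equal(sd(as.vector(out$data[i, , ])), 1, tolerance = 1e-9)
  expect_equal(out$data[1, , ], out$data[2, , ], tolerance = 1e-12)
  flat <- toy_cube(); flat$data[1, , ] <- 2
  expect_error(normalize_sample_variance(flat), "zero variance")
})

test_that("unfold/refold is the documented emission-fastest bijection", {
  slab <- matrix(1:6, 2, 3)           # 2 emission x 3 excitation
  cube <- eem_cube(array(slab, c(1, 2, 3)), c(300, 310), c(250, 260, 270))
  v <- unfold(cube)[1, ]
  expect_equal(unname(v), c(1, 2, 3, 4, 5, 6))  # em fastest within each ex
  expect_equal(unname(refold(v, cube$em_axis, cube$ex_axis)), slab)
  big <- toy_cube(n = 4, seed = 9)
  U <- unfold(big)
  for (i in 1:4)
    expect_identical(unname(refold(U[i, ], big$em_axis, big$ex_axis)),
                     big$data[i, , ])
})

test_that("refolded principal loading of a rank-1 cube is the em/ex outer product", {
  em <- seq(250, 400, 5); ex <- seq(250, 350, 10)
  emp <- exp(-0.5 * ((em - 330) / 25)^2)
  exp_ <- exp(-0.5 * ((ex - 290) / 20)^2)
  set.seed(3)
  sc <- runif(12, 0.5, 2)
  data <- array(0, c(12, length(em), length(ex)))
  for (i in 1:12) data[i, , ] <- sc[i] * emp %o% exp_
  cube <- eem_cube(data, em, ex)
  v1 <- svd(unfold(cube), nu = 0, nv = 1)$v[, 1]
  truth <- as.vector(emp %o% exp_)
  expect_gt(abs(congruence(v1, truth)), 0.999)
})

test_that("region cropping restricts the axes and rejects disjoint regions", {
  em <- seq(250, 550, 2); ex <- seq(250, 450, 10)
  cube <- eem_cube(array(1, c(2, length(em), length(ex))), em, ex)
  b <- crop_region(cube, region_spec(c(250, 400), c(370, 530), "Region B"))
  expect_true(min(b$ex_axis) >= 250 && max(b$ex_axis) <= 400)
  expect_true(min(b$em_axis) >= 370 && max(b$em_axis) <= 530)
  full <- crop_region(cube, region_spec(c(250, 450), c(250, 550)))
  expect_identical(full$data, cube$data)
  expect_error(crop_region(cube, region_spec(c(600, 700), c(600, 700))),
               "does not intersect")
})
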