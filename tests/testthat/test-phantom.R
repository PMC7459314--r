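# Orientation sampling and phantom generation against closed-form and
# Monte-Carlo oracles.

test_that("vMF sampling honours the concentration limits", {
  # near-degenerate concentration: everything within 0.01 rad of the pole
  v <- sample_orientations(1000, c(1, 0, 0), kappa = 1e6, seed = 1)
  expect_true(all(abs(v[, 1] - 1) < 1e-4))
  angles <- acos(pmin(1, v[, 1]))
  expect_lt(max(angles), 0.01)
  expect_equal(sqrt(rowSums(v^2)), rep(1, 1000), tolerance = 1e-12)

  # kappa = 0: uniform on the sphere, mean resultant length near zero
  u <- sample_orientations(1e5, c(1, 0, 0), kappa = 0, seed = 2)
  expect_lt(sqrt(sum(colMeans(u)^2)), 0.02)
})

test_that("vMF mean cosine matches the closed form coth(k) - 1/k", {
  # E[cos theta] for kappa = 2 is coth(2) - 1/2 = 0.5373
  v <- sample_orientations(1e5, c(1, 0, 0), kappa = 2, seed = 3)
  expect_equal(mean(v[, 1]), 1 / tanh(2) - 1 / 2, tolerance = 0.01)
  # off-pole mean axis: mean cosine to that axis obeys the same law
  ax <- c(1, 2, 2) / 3
  w <- sample_orientations(1e5, ax, kappa = 2, seed = 4)
  expect_equal(mean(w %*% ax), 1 / tanh(2) - 1 / 2, tolerance = 0.01)
})

test_that("orientation sampling rejects bad inputs", {
  expect_error(sample_orientations(10, c(1, 1, 0), kappa = 1), "unit norm")
  expect_error(sample_orientations(10, c(1, 0, 0), kappa = -1), "kappa")
})

test_that("uniform-sphere truth versors give disarray 0.5 after canonicalization", {
  v <- sample_orientations(1e5, c(1, 0, 0), kappa = 0, seed = 5)
  expect_equal(versor_disarray(v), 0.5, tolerance = 0.02)
})

test_that("single straight tube truth matches the cylinder closed form", {
  line <- matrix(c(50, 50, 0, 50, 50, 100), 2, 3, byrow = TRUE)
  attr(line, "diameter_um") <- 6
  spec <- phantom_spec(volume_size_um = c(101, 101, 101),
                       centerlines = list(line), tortuosity = 0,
                       noise_sd = 0, seed = 1)
  ph <- generate_phantom(spec)
  expect_equal(ph$truth$surface_um2, 2 * pi * 3 * 100, tolerance = 1e-10)
  expect_equal(ph$truth$volume_um3, pi * 9 * 100, tolerance = 1e-10)
  # discretized mask isosurface area within 2% of the analytic lateral area
  area <- mask_isosurface_area(ph$truth$vessel_mask)
  expect_equal(area, 2 * pi * 3 * 100, tolerance = 0.02)
})

test_that("non-overlapping straight tubes keep analytic surface additivity", {
  l1 <- matrix(c(25, 25, 0, 25, 25, 101), 2, 3, byrow = TRUE)
  l2 <- matrix(c(75, 75, 0, 75, 75, 101), 2, 3, byrow = TRUE)
  attr(l1, "diameter_um") <- 6; attr(l2, "diameter_um") <- 4
  spec <- phantom_spec(volume_size_um = c(101, 101, 101),
                       centerlines = list(l1, l2), tortuosity = 0,
                       noise_sd = 0, seed = 1)
  ph <- generate_phantom(spec)
  expect_equal(ph$truth$surface_um2, pi * 6 * 101 + pi * 4 * 101,
               tolerance = 1e-10)
  area <- mask_isosurface_area(ph$truth$vessel_mask)
  expect_equal(area, ph$truth$surface_um2, tolerance = 0.02)
})

test_that("collagen channel hits the requested fraction exactly pre-blur", {
  ph0 <- quick_phantom(seed = 6, collagen_fraction = 0)
  expect_identical(ph0$truth$collagen_fraction, 0)
  expect_true(!any(ph0$truth$collagen_mask))
  ph <- quick_phantom(seed = 6, collagen_fraction = 0.1)
  expect_equal(ph$truth$collagen_fraction, 0.1, tolerance = 0.005)
})

test_that("identical spec and seed reproduce the phantom exactly", {
  a <- quick_phantom(seed = 9)
  b <- quick_phantom(seed = 9)
  expect_identical(a$vessel$data, b$vessel$data)
  expect_identical(a$cell$data, b$cell$data)
  expect_identical(a$collagen$data, b$collagen$data)
  expect_identical(a$truth$diameters_um, b$truth$diameters_um)
  d <- quick_phantom(seed = 10)
  expect_false(identical(a$vessel$data, d$vessel$data))
})

test_that("generation does not disturb the session RNG", {
  set.seed(123)
  before <- .Random.seed
  invisible(quick_phantom(seed = 4))
  expect_identical(.Random.seed, before)
})

test_that("impossible densities are rejected with a capacity message", {
  expect_error(
    generate_phantom(phantom_spec(volume_size_um = c(40, 40, 40),
                                  n_vessels = 500,
                                  vessel_diameter_um = c(12, 0), seed = 1)),
    "capacity")
  expect_error(phantom_spec(collagen_fraction = 1.2), "collagen_fraction")
  expect_error(phantom_spec(kappa = -2), "kappa")
})

test_that("phantom truth versors live in the +z hemisphere", {
  ph <- quick_phantom(seed = 11, kappa = 0.5)
  v <- ph$truth$vessel_orientations
  expect_true(all(v[, 1] > 0 | (v[, 1] == 0 & v[, 2] >= 0)))
  expect_equal(sqrt(rowSums(v^2)), rep(1, nrow(v)), tolerance = 1e-9)
})

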