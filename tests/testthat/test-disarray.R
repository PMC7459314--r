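# Structure-tensor orientation extraction and the disarray statistic.

test_that("disarray limits: identical, orthogonal and hemisphere-uniform versors", {
  # identical versors: alignment 1, disarray exactly 0
  v <- matrix(rep(c(0, 0, 1), 8), ncol = 3, byrow = TRUE)
  expect_identical(versor_disarray(v), 0)
  # orthogonal pair: 1 - |(0.5, 0.5, 0)| = 1 - 1/sqrt(2)
  p <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(versor_disarray(p), 1 - 1 / sqrt(2), tolerance = 1e-6)
  # uniform hemisphere: mean resultant length 1/2
  set.seed(8)
  u <- matrix(rnorm(3e5), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  expect_equal(versor_disarray(u), 0.5, tolerance = 0.02)
})

test_that("disarray is antipodally invariant", {
  set.seed(9)
  v <- sample_orientations(500, c(1, 0, 0), kappa = 3)
  flip <- sample(c(-1, 1), 500, replace = TRUE)
  expect_equal(versor_disarray(v * flip), versor_disarray(v),
               tolerance = 1e-12)
})

test_that("a tube along x yields a block versor within 5 degrees of (0,0,1)", {
  line <- matrix(c(32, 32, 0, 32, 32, 64), 2, 3, byrow = TRUE)
  attr(line, "diameter_um") <- 8
  ph <- generate_phantom(phantom_spec(volume_size_um = c(64, 64, 64),
                                      centerlines = list(line),
                                      tortuosity = 0, noise_sd = 0.02,
                                      seed = 2))
  fld <- block_orientations(ph$vessel, block_size_um = 64,
                            gradient_sigma_um = 2)
  b <- fld$blocks[fld$blocks$valid, ]
  expect_identical(nrow(b), 1L)
  ang <- acos(pmin(1, abs(sum(unlist(b[c("vz", "vy", "vx")]) * c(0, 0, 1)))))
  expect_lt(ang, 5 * pi / 180)
})

test_that("noise-only and constant blocks are marked invalid", {
  set.seed(5)
  g <- as_grid(array(runif(40^3), rep(40, 3)))
  fld <- block_orientations(g, block_size_um = 40, gradient_sigma_um = 2)
  expect_false(any(fld$blocks$valid))
  gc <- as_grid(array(0.5, rep(40, 3)))
  fldc <- block_orientations(gc, block_size_um = 40)
  expect_false(any(fldc$blocks$valid))
})

test_that("local disarray groups blocks and global is their mean", {
  expect_identical(global_disarray(c(0, 0, 0)), 0)
  expect_equal(global_disarray(c(0.2, 0.4)), 0.3)
  expect_error(global_disarray(numeric(0)), "no local")
  # super-block must be commensurate with the block size
  ph <- quick_phantom(seed = 3)
  fld <- block_orientations(ph$vessel, block_size_um = 32)
  expect_error(local_disarray(fld, super_block_um = 50), "integer multiple")
  dz <- local_disarray(fld, super_block_um = 64)
  expect_identical(dz$global_disarray, mean(dz$local_disarray))
  expect_true(all(dz$local_disarray >= 0 & dz$local_disarray <= 1))
})

test_that("block size exceeding the volume is rejected", {
  ph <- quick_phantom(seed = 3)
  expect_error(block_orientations(ph$vessel, block_size_um = 100),
               "exceeds")
})

test_that("global disarray responds monotonically to orientation dispersion", {
  # concentrated (kappa 50) vs dispersed (kappa 2) tube networks
  d <- vapply(c(50, 2), function(k) {
    ph <- generate_phantom(phantom_spec(kappa = k, seed = 13))
    local_disarray(block_orientations(ph$vessel))$global_disarray
  }, numeric(1))
  expect_gt(d[2], d[1])
})

test_that("rotating the stack by 90 degrees leaves global disarray unchanged", {
  ph <- generate_phantom(phantom_spec(volume_size_um = c(96, 96, 96),
                                      n_vessels = 25, kappa = 4, seed = 17))
  dz0 <- local_disarray(block_orientations(ph$vessel, block_size_um = 48),
                        super_block_um = 96)$global_disarray
  rot <- aperm(ph$vessel$data, c(2, 1, 3))  # 90-degree rotation in the z-y plane
  rot <- rot[dim(rot)[1]:1, , ]
  dz1 <- local_disarray(block_orientations(as_grid(rot), block_size_um = 48),
                        super_block_um = 96)$global_disarray
  expect_equal(dz1, dz0, tolerance = 0.02)
})

test_that("the dyadic alternative agrees at the aligned and isotropic limits", {
  v <- matrix(rep(c(0, 0.6, 0.8), 10), ncol = 3, byrow = TRUE)
  fld <- structure(list(blocks = data.frame(iz = 1:10, iy = 1, ix = 1,
                                            vz = v[, 1], vy = v[, 2],
                                            vx = v[, 3], anisotropy = 1,
                                            signal_fraction = 1,
                                            n_voxels = 1, valid = TRUE),
                        block_size_um = 60, block_vox = 60,
                        grid_dim = c(600, 60, 60), pitch_um = 1),
                   class = "orientation_field")
  expect_equal(local_disarray(fld, 600, method = "vector")$global_disarray, 0)
  expect_equal(local_disarray(fld, 600, method = "dyadic")$global_disarray, 0,
               tolerance = 1e-9)
})
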