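# Otsu threshold, binarization and skeletonization against brute-force and phantom-truth oracles.

test_that("two-valued volumes threshold between the classes", {
  x <- array(rep(c(0, 200), each = 500), c(10, 10, 10))
  t <- otsu_threshold(as_grid(x))
  expect_gt(t, 0); expect_lt(t, 200)
  m <- binarize(as_grid(x), t)
  expect_identical(m$data, x > 100)
})

test_that("Otsu equals the exhaustive-search oracle on random mixtures", {
  for (s in 1:10) {
    set.seed(s)
    x <- array(c(rnorm(600, 50, 10), rnorm(400, 180, 10)), c(10, 10, 10))
    expect_identical(otsu_threshold(as_grid(x)), otsu_oracle(x))
  }
})

test_that("constant volumes are rejected, binarization convention is strict", {
  expect_error(otsu_threshold(as_grid(array(1, c(4, 4, 4)))), "constant")
  g <- as_grid(array(0, c(4, 4, 4)))
  expect_false(any(binarize(g, 0.5)$data))
  g2 <- as_grid(array(runif(64), c(4, 4, 4)))
  expect_false(any(binarize(g2, max(g2$data))$data))  # strictly greater
})

test_that("high-SNR phantom tube stacks segment with Dice >= 0.95", {
  ph <- generate_phantom(phantom_spec(seed = 5, noise_sd = 0.02))
  mask <- binarize(ph$vessel, otsu_threshold(ph$vessel))$data
  tr <- ph$truth$vessel_mask
  dice <- 2 * sum(mask & tr) / (sum(mask) + sum(tr))
  expect_gte(dice, 0.95)
})

test_that("a straight cylinder reduces to one full-length segment", {
  m <- binary_mask(cylinder_mask(n = 101, radius_um = 3, axis = 3), 1)
  g <- skeletonize(m)
  expect_length(g$segments, 1)
  expect_equal(g$segments[[1]]$length_um, 100, tolerance = 0.05)
})

test_that("a Y-junction yields three segments around one degree-3 node", {
  g <- skeletonize(binary_mask(y_junction_mask(), 1))
  expect_length(g$segments, 3)
  junctions <- g$nodes[g$nodes$kind == "junction", ]
  expect_identical(nrow(junctions), 1L)
  expect_equal(junctions$degree, 3)
})

test_that("an already-thin line is its own skeleton", {
  arr <- array(FALSE, c(30, 9, 9))
  arr[3:28, 5, 5] <- TRUE
  g <- skeletonize(binary_mask(arr, 1), min_component_voxels = 1,
                   prune_spurs_um = 0)
  expect_identical(sort(which(g$skeleton)), sort(which(arr)))
  expect_length(g$segments, 1)
})

test_that("skeletons are invariant under axis permutation of the phantom", {
  lens <- vapply(1:3, function(ax) {
    m <- binary_mask(cylinder_mask(n = 61, radius_um = 3, axis = ax), 1)
    g <- skeletonize(m)
    expect_length(g$segments, 1)
    g$segments[[1]]$length_um
  }, numeric(1))
  expect_equal(lens, rep(lens[1], 3))
})

test_that("cylinder radius and volume are recovered from the distance transform", {
  # sample the sub-voxel placements of the axis: the digitized distance
  # transform is unbiased over placements but quantized for any single one
  vols <- vapply(c(0, 0.25, 0.5), function(off) {
    line <- matrix(c(50 + off, 50 + off, 0, 50 + off, 50 + off, 100),
                   2, 3, byrow = TRUE)
    m <- binary_mask(rasterize_tubes(list(line), 6, rep(101, 3), 1), 1)
    g <- measure_segments(skeletonize(m), m)
    st <- segment_table(g)
    # radius within half a voxel pitch of the true 3 um, every placement
    expect_equal(st$mean_radius_um, 3, tolerance = 0.5 / 3)
    sum(st$volume_um3)
  }, numeric(1))
  # volume within 10% of pi r^2 L on average over placements
  expect_equal(mean(vols), pi * 9 * 100, tolerance = 0.10)
})

test_that("an isolated voxel survives as a degenerate segment", {
  arr <- array(FALSE, c(9, 9, 9)); arr[5, 5, 5] <- TRUE
  g <- measure_segments(skeletonize(binary_mask(arr, 1),
                                    min_component_voxels = 1,
                                    prune_spurs_um = 0),
                        binary_mask(arr, 1))
  expect_length(g$segments, 1)
  expect_identical(g$segments[[1]]$length_um, 0)
  expect_equal(g$segments[[1]]$mean_radius_um, 1, tolerance = 0.01)
  expect_identical(g$segments[[1]]$volume_um3, 0)
})

test_that("per-segment volumes approximate the mask volume on a non-branching tube", {
  m <- binary_mask(cylinder_mask(n = 81, radius_um = 4, axis = 2), 1)
  g <- measure_segments(skeletonize(m), m)
  mask_vol <- sum(m$data)  # pitch 1: um^3
  expect_equal(sum(segment_table(g)$volume_um3), mask_vol, tolerance = 0.15)
})

test_that("estimated radii preserve the ordering of true tube diameters", {
  mk <- function(d, y) {
    line <- matrix(c(40, y, 0, 40, y, 81), 2, 3, byrow = TRUE)
    attr(line, "diameter_um") <- d
    line
  }
  spec <- phantom_spec(volume_size_um = c(81, 81, 81),
                       centerlines = list(mk(4, 15), mk(6, 40), mk(9, 66)),
                       tortuosity = 0, noise_sd = 0.05, seed = 3)
  ph <- generate_phantom(spec)
  mask <- filter_small_components(binarize(ph$vessel,
                                           otsu_threshold(ph$vessel)), 10)
  g <- measure_segments(skeletonize(mask), mask)
  st <- segment_table(g)
  st <- st[st$length_um > 5, ]  # the three tubes (not stray fragments)
  st <- st[order(st$mean_radius_um), ]
  expect_identical(nrow(st), 3L)
  expect_true(all(diff(st$mean_radius_um) > 0))
})

test_that("anisotropic masks are rejected before skeletonization", {
  arr <- array(TRUE, c(4, 4, 4))
  expect_error(skeletonize(binary_mask(arr, c(2, 1, 1))), "isotropic")
})
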