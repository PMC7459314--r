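# Shared fixtures, all built in code.

# straight axis-aligned cylinder mask: axis along `axis` (1 = z, 2 = y,
# 3 = x) through the lateral centre of a cubic volume
cylinder_mask <- function(n = 101, pitch = 1, radius_um = 3, axis = 3,
                          length_um = (n - 1) * pitch) {
  ctr <- (n - 1) * pitch / 2
  p0 <- rep(ctr, 3); p1 <- rep(ctr, 3)
  p0[axis] <- 0; p1[axis] <- length_um
  line <- rbind(p0, p1)
  rasterize_tubes(list(line), 2 * radius_um, rep(n, 3), pitch)
}

# three tubes meeting at a single point (Y junction)
y_junction_mask <- function(n = 121, pitch = 1, diameter_um = 6) {
  ctr <- c(60, 60, 60)
  arms <- list(rbind(c(60, 60, 5), ctr),
               rbind(ctr, c(100, 20, 100)),
               rbind(ctr, c(20, 20, 100)))
  rasterize_tubes(arms, rep(diameter_um, 3), rep(n, 3), pitch)
}

# small, quick phantom for pipeline-level tests
quick_phantom <- function(seed, ...) {
  generate_phantom(phantom_spec(volume_size_um = c(64, 64, 64),
                                n_vessels = 8, seed = seed, ...))
}

as_grid <- function(arr, pitch = 1, channel = "vessel") {
  voxel_grid(arr, pitch, channel)
}

# helper: isosurface area of a binary mask at unit pitch via the package's
# triangulation with its validated smoothing
mask_isosurface_area <- function(mask) {
  m <- binary_mask(mask, 1)
  surface_density(m) * prod(dim(mask))
}
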