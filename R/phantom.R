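# Synthetic three-channel stacks with exact ground truth.  The generator
# emulates cleared-ventricle two-photon acquisitions: a gel-filled capillary
# network (bright tubes), myocyte rods, and speckled fibrillar collagen, on
# an isotropic grid, optionally downsampled along z to mimic the coarse
# acquisition z-step.

#' Specification of one synthetic stack
#'
#' All coordinate triples are (z, y, x); direction versors likewise.
#'
#' @param volume_size_um physical extent (z, y, x) in um.
#' @param voxel_pitch_um isotropic generation pitch in um.
#' @param n_vessels number of capillary centerlines.
#' @param vessel_diameter_um `c(mean, sd)` of tube diameter in um.
#' @param target_surface_density_um_inv optional: instead of `n_vessels`,
#'   draw tubes until the analytic lateral surface per stack volume reaches
#'   this value (um^-1).
#' @param mean_axis preferred tube/rod direction, unit (z, y, x) versor; the default points along +z, the pole of the hemisphere convention used for axial averaging (a mean axis near the equator of that convention is valid but makes the vector-mean alignment of its own cluster pessimistic).
#' @param kappa von Mises-Fisher concentration of vessel axes (0 = isotropic).
#' @param kappa_cell concentration of cell-rod axes (defaults to `kappa`).
#' @param tortuosity amplitude (um) of the smooth sinusoidal centerline
#'   perturbation; 0 gives straight tubes.
#' @param cell_rod_dims_um `c(length, width)` of myocyte rods in um.
#' @param cell_fill_fraction target rod volume fraction of the cell channel.
#' @param collagen_fraction target collagen volume fraction in \[0, 1\].
#' @param psf_sigma_um Gaussian blur scale (um), scalar or per axis (z, y, x).
#' @param noise_sd additive Gaussian noise sd (intensity units; signal
#'   amplitude is `signal_level - background_level`).
#' @param poisson_scale optional photon-count scaling; when set, intensities
#'   are Poisson-resampled as `rpois(scale * I) / scale` before the Gaussian
#'   noise.
#' @param signal_level,background_level clean foreground / background
#'   intensities (kept inside \[0, 1\] so stacks are storable as TIFF).
#' @param axial_pitch_um optional coarser z pitch to emulate the microscope's
#'   z-step: planes are subsampled so the z pitch becomes this value (must be
#'   an integer multiple of `voxel_pitch_um`).
#' @param centerlines optional list of polylines (matrices of (z, y, x) um
#'   coordinates) overriding random centerline generation; diameters are
#'   drawn from `vessel_diameter_um` unless an attribute `diameter_um` is set
#'   on a polyline.
#' @param seed integer RNG seed; identical spec + seed gives identical output.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_size_um = c(128, 128, 128),
                         voxel_pitch_um = 1,
                         n_vessels = 50,
                         vessel_diameter_um = c(mean = 6, sd = 0.5),
                         target_surface_density_um_inv = NULL,
                         mean_axis = c(1, 0, 0),
                         kappa = 20,
                         kappa_cell = NULL,
                         tortuosity = 3,
                         cell_rod_dims_um = c(length = 80, width = 15),
                         cell_fill_fraction = 0.5,
                         collagen_fraction = 0.08,
                         psf_sigma_um = 1,
                         noise_sd = 0.08,
                         poisson_scale = NULL,
                         signal_level = 0.85,
                         background_level = 0.05,
                         axial_pitch_um = NULL,
                         centerlines = NULL,
                         seed = 1L) {
  spec <- list(volume_size_um = as.numeric(volume_size_um),
               voxel_pitch_um = as.numeric(voxel_pitch_um),
               n_vessels = as.integer(n_vessels),
               vessel_diameter_um = as.numeric(vessel_diameter_um),
               target_surface_density_um_inv = target_surface_density_um_inv,
               mean_axis = as.numeric(mean_axis),
               kappa = as.numeric(kappa),
               kappa_cell = if (is.null(kappa_cell)) as.numeric(kappa)
                            else as.numeric(kappa_cell),
               tortuosity = as.numeric(tortuosity),
               cell_rod_dims_um = as.numeric(cell_rod_dims_um),
               cell_fill_fraction = as.numeric(cell_fill_fraction),
               collagen_fraction = as.numeric(collagen_fraction),
               psf_sigma_um = as.numeric(psf_sigma_um),
               noise_sd = as.numeric(noise_sd),
               poisson_scale = poisson_scale,
               signal_level = as.numeric(signal_level),
               background_level = as.numeric(background_level),
               axial_pitch_um = axial_pitch_um,
               centerlines = centerlines,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(volume_size_um) != 3 || any(volume_size_um <= 0))
      stop("volume_size_um must be a positive (z, y, x) triple")
    if (voxel_pitch_um <= 0) stop("voxel_pitch_um must be > 0")
    if (collagen_fraction < 0 || collagen_fraction > 1)
      stop("collagen_fraction must lie in [0, 1]")
    if (kappa < 0 || kappa_cell < 0) stop("kappa must be >= 0")
    if (abs(sqrt(sum(mean_axis^2)) - 1) > 1e-6)
      stop("mean_axis must have unit norm")
    if (vessel_diameter_um[1] <= 0) stop("vessel diameter must be > 0")
    if (!is.null(axial_pitch_um)) {
      k <- axial_pitch_um / voxel_pitch_um
      if (abs(k - round(k)) > 1e-9 || round(k) < 1)
        stop("axial_pitch_um must be an integer multiple of voxel_pitch_um")
    }
  })
  invisible(spec)
}

#' Sample unit orientation versors from a von Mises-Fisher distribution
#'
#' `kappa = 0` gives the uniform distribution on the sphere; large `kappa`
#' concentrates around `mean_axis`.  Sampling uses the inverse-CDF of the
#' cosine to the mean axis (exact for the 2-sphere).
#'
#' @param n number of versors (>= 1).
#' @param mean_axis unit (z, y, x) direction.
#' @param kappa concentration parameter, >= 0.
#' @param seed optional integer; when given, sampling runs in a private RNG
#'   stream and the session RNG is untouched.
#' @return `n` x 3 matrix of unit versors, (z, y, x) order.
#' @export
sample_orientations <- function(n, mean_axis = c(1, 0, 0), kappa, seed = NULL) {
  stopifnot(n >= 1)
  if (kappa < 0) stop("kappa must be >= 0")
  if (abs(sqrt(sum(mean_axis^2)) - 1) > 1e-6)
    stop("mean_axis must have unit norm")
  draw <- function() {
    if (kappa == 0) {
      v <- matrix(rnorm(3 * n), ncol = 3)
      v / sqrt(rowSums(v^2))
    } else {
      u <- runif(n)
      # cos(angle to mean); exp(-2*kappa) underflows harmlessly at large kappa
      w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
      w <- pmax(pmin(w, 1), -1)
      phi <- runif(n, 0, 2 * pi)
      s <- sqrt(pmax(0, 1 - w^2))
      local <- cbind(w, s * cos(phi), s * sin(phi))
      local %*% t(rotation_from_z(mean_axis))
    }
  }
  v <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  v / sqrt(rowSums(v^2))
}

# Rotation matrix mapping the local pole e1 = (1,0,0) [the first component,
# i.e. +z in (z,y,x) order] onto unit vector b (Rodrigues formula).
rotation_from_z <- function(b) {
  a <- c(1, 0, 0)
  cv <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(cv^2))
  cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    return(diag(c(-1, -1, 1)))  # any 180-degree rotation about an axis
  }
  K <- matrix(c(0, -cv[3], cv[2],
                cv[3], 0, -cv[1],
                -cv[2], cv[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

# Clip the line p + t*d to the axis-aligned box [0, size]; returns c(t0, t1)
# or NULL when the line misses the box.
clip_line_to_box <- function(p, d, size) {
  t0 <- -Inf; t1 <- Inf
  for (a in 1:3) {
    if (abs(d[a]) < 1e-12) {
      if (p[a] < 0 || p[a] > size[a]) return(NULL)
    } else {
      ta <- (0 - p[a]) / d[a]
      tb <- (size[a] - p[a]) / d[a]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
    }
  }
  if (t1 <= t0) return(NULL)
  c(t0, t1)
}

# Build one centerline polyline: vMF direction, uniform anchor, clipped to
# the volume, plus a transverse sinusoidal perturbation of amplitude
# `tortuosity` um (one wave per ~100 um, random phase).
make_centerline <- function(size, mean_axis, kappa, tortuosity, step_um = 2) {
  repeat {
    d <- as.numeric(sample_orientations(1, mean_axis, kappa))
    p <- runif(3) * size
    tt <- clip_line_to_box(p, d, size)
    if (!is.null(tt) && diff(tt) >= 4 * step_um) break
  }
  ts <- seq(tt[1], tt[2], by = step_um)
  if (ts[length(ts)] < tt[2]) ts <- c(ts, tt[2])
  pts <- t(vapply(ts, function(t) p + t * d, numeric(3)))
  if (tortuosity > 0) {
    # orthonormal frame transverse to d
    u <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- u - sum(u * d) * d; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(d[2] * e1[3] - d[3] * e1[2],
            d[3] * e1[1] - d[1] * e1[3],
            d[1] * e1[2] - d[2] * e1[1])
    lam <- 100  # wavelength um
    ph <- runif(2, 0, 2 * pi)
    arc <- ts - ts[1]
    off <- tortuosity * (sin(2 * pi * arc / lam + ph[1]) %o% e1 +
                         cos(2 * pi * arc / lam + ph[2]) %o% e2)
    pts <- pts + off
    pts <- pmin(pmax(pts, 0), matrix(size, nrow(pts), 3, byrow = TRUE))
  }
  attr(pts, "direction") <- d
  pts
}

polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Generate a synthetic three-channel stack with ground truth
#'
#' Produces vessel, cell and collagen channels plus a `truth` list holding
#' the exact generative quantities: per-vessel centerlines and diameters,
#' analytic surface/volume, orientation versors (canonicalized to the +z
#' hemisphere) with their angular dispersion, the exact collagen voxel
#' fraction, the cell-rod orientations, and the pre-blur binary masks.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom`: `vessel`, `cell`, `collagen`
#'   ([voxel_grid()]s), `truth`, `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  with_local_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  size <- spec$volume_size_um
  pitch <- spec$voxel_pitch_um
  dims <- pmax(2L, as.integer(round(size / pitch)))
  vol_um3 <- prod(dims * pitch)

  ## ---- vessels -------------------------------------------------------
  dmean <- spec$vessel_diameter_um[1]
  dsd <- if (length(spec$vessel_diameter_um) > 1) spec$vessel_diameter_um[2] else 0
  lines <- list(); diams <- numeric(0)
  if (!is.null(spec$centerlines)) {
    lines <- spec$centerlines
    diams <- vapply(lines, function(p) {
      d <- attr(p, "diameter_um")
      if (is.null(d)) max(1, rnorm(1, dmean, dsd)) else d
    }, numeric(1))
  } else if (!is.null(spec$target_surface_density_um_inv)) {
    target <- spec$target_surface_density_um_inv * vol_um3
    acc <- 0
    while (acc < target) {
      p <- make_centerline(size, spec$mean_axis, spec$kappa, spec$tortuosity)
      di <- max(1, rnorm(1, dmean, dsd))
      lines[[length(lines) + 1]] <- p
      diams <- c(diams, di)
      acc <- acc + pi * di * polyline_length(p)
      if (length(lines) > 5000)
        stop("requested surface density is geometrically unattainable in this volume")
    }
  } else {
    for (i in seq_len(spec$n_vessels)) {
      lines[[i]] <- make_centerline(size, spec$mean_axis, spec$kappa,
                                    spec$tortuosity)
      diams[i] <- max(1, rnorm(1, dmean, dsd))
    }
  }
  lens <- vapply(lines, polyline_length, numeric(1))
  if (sum(pi * (diams / 2)^2 * lens) > 0.5 * vol_um3)
    stop("requested vascular density exceeds the geometric capacity of the volume")

  vessel_mask <- rasterize_tubes(lines, diams, dims, pitch)
  vdirs <- t(vapply(lines, function(p) {
    d <- attr(p, "direction")
    if (is.null(d)) {  # user-supplied polyline: end-to-end chord
      d <- p[nrow(p), ] - p[1, ]
      d <- d / sqrt(sum(d^2))
    }
    d
  }, numeric(3)))
  vdirs <- canonicalize_versors(vdirs)

  ## ---- cells ---------------------------------------------------------
  rod_l <- spec$cell_rod_dims_um[1]
  rod_w <- spec$cell_rod_dims_um[2]
  rod_vol <- pi * (rod_w / 2)^2 * (rod_l - rod_w) + 4 / 3 * pi * (rod_w / 2)^3
  n_cells <- max(1L, as.integer(round(spec$cell_fill_fraction * vol_um3 / rod_vol)))
  cdirs <- sample_orientations(n_cells, spec$mean_axis, spec$kappa_cell)
  centers <- matrix(runif(3 * n_cells), ncol = 3) *
    matrix(size, n_cells, 3, byrow = TRUE)
  half <- (rod_l - rod_w) / 2
  p0 <- centers - half * cdirs
  p1 <- centers + half * cdirs
  cell_mask <- array(FALSE, dims)
  cell_mask <- cpp_rasterize_capsules(cell_mask, as.integer(dims), pitch,
                                      p0, p1, rep(rod_w / 2, n_cells))
  dim(cell_mask) <- dims
  cdirs <- canonicalize_versors(cdirs)

  ## ---- collagen ------------------------------------------------------
  if (spec$collagen_fraction <= 0) {
    collagen_mask <- array(FALSE, dims)
  } else if (spec$collagen_fraction >= 1) {
    collagen_mask <- array(TRUE, dims)
  } else {
    field <- gaussian_blur(array(rnorm(prod(dims)), dims), 3 / pitch)
    thr <- quantile(field, 1 - spec$collagen_fraction, names = FALSE)
    collagen_mask <- field > thr
  }

  ## ---- render channels ----------------------------------------------
  render <- function(mask) {
    x <- spec$background_level +
      (spec$signal_level - spec$background_level) * as.numeric(mask)
    dim(x) <- dims
    sig_vox <- spec$psf_sigma_um / pitch
    if (any(sig_vox > 0)) x <- gaussian_blur(x, sig_vox)
    if (!is.null(spec$poisson_scale)) {
      s <- spec$poisson_scale
      x[] <- rpois(length(x), s * pmax(x, 0)) / s
    }
    if (spec$noise_sd > 0) x <- x + rnorm(length(x), 0, spec$noise_sd)
    x <- pmin(pmax(x, 0), 1)
    dim(x) <- dims
    x
  }
  chans <- list(vessel = render(vessel_mask),
                cell = render(cell_mask),
                collagen = render(collagen_mask))

  ## ---- optional axial downsampling ----------------------------------
  pitch3 <- rep(pitch, 3)
  if (!is.null(spec$axial_pitch_um)) {
    k <- as.integer(round(spec$axial_pitch_um / pitch))
    keep <- seq(1, dims[1], by = k)
    chans <- lapply(chans, function(x) x[keep, , , drop = FALSE])
    pitch3 <- c(spec$axial_pitch_um, pitch, pitch)
  }

  truth <- list(
    centerlines = lines,
    diameters_um = diams,
    lengths_um = lens,
    surface_um2 = sum(pi * diams * lens),
    volume_um3 = sum(pi * (diams / 2)^2 * lens),
    vessel_orientations = vdirs,
    angular_dispersion = versor_disarray(vdirs, canonicalize = FALSE),
    cell_orientations = cdirs,
    cell_disarray = versor_disarray(cdirs, canonicalize = FALSE),
    collagen_fraction = mean(collagen_mask),
    vessel_mask = vessel_mask,
    cell_mask = cell_mask,
    collagen_mask = collagen_mask)

  structure(list(
    vessel = voxel_grid(chans$vessel, pitch3, "vessel", "phantom"),
    cell = voxel_grid(chans$cell, pitch3, "cell", "phantom"),
    collagen = voxel_grid(chans$collagen, pitch3, "collagen", "phantom"),
    truth = truth,
    spec = spec), class = "phantom")
}

#' Rasterize tube centerlines into a binary mask
#'
#' A voxel is foreground when its centre lies within diameter/2 of the
#' polyline (point-to-segment distance), matching the distance-transform
#' radius estimator used downstream.
#'
#' @param centerlines list of polylines, each an m x 3 matrix of (z, y, x)
#'   um coordinates.
#' @param diameters_um one diameter per polyline.
#' @param dims voxel grid dimensions (z, y, x).
#' @param pitch_um isotropic voxel pitch.
#' @return logical 3D array.
#' @export
rasterize_tubes <- function(centerlines, diameters_um, dims, pitch_um) {
  p0 <- do.call(rbind, lapply(centerlines, function(p) p[-nrow(p), , drop = FALSE]))
  p1 <- do.call(rbind, lapply(centerlines, function(p) p[-1, , drop = FALSE]))
  nseg <- vapply(centerlines, nrow, integer(1)) - 1L
  r <- rep(diameters_um / 2, nseg)
  mask <- array(FALSE, dims)
  mask <- cpp_rasterize_capsules(mask, as.integer(dims), pitch_um, p0, p1, r)
  dim(mask) <- dims
  mask
}

#' Write a phantom to disk (TIFF channels + JSON spec/truth)
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in c("vessel", "cell", "collagen"))
    write_stack(phantom[[ch]], file.path(dir, paste0(ch, ".tif")))
  spec <- phantom$spec
  spec$centerlines <- NULL
  jsonlite::write_json(spec, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  truth <- phantom$truth
  truth$vessel_mask <- truth$cell_mask <- truth$collagen_mask <- NULL
  truth$centerlines <- lapply(truth$centerlines, unclass)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
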