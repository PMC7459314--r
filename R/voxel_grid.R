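# Single-channel 3D intensity volumes with physical pitch metadata.
# Convention used package-wide: array dimensions and coordinate triples are
# ordered (z, y, x), indices are voxel centres, the centre of voxel [1,1,1]
# sits at physical coordinate (0, 0, 0) um.

#' Construct a voxel grid
#'
#' @param data 3D numeric array, dimension order (z, y, x).
#' @param pitch_um voxel pitch in um: scalar (isotropic) or triple (z, y, x).
#' @param channel which stain the channel carries: `"vessel"` (lumen gel
#'   fill), `"cell"` (membrane stain, or its negative), `"collagen"`
#'   (second-harmonic signal).
#' @param provenance free-text source identifier.
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, pitch_um,
                       channel = c("vessel", "cell", "collagen"),
                       provenance = "") {
  channel <- match.arg(channel)
  if (length(dim(data)) != 3)
    stop("`data` must be a 3D array (got ", length(dim(data)), " dimensions)")
  if (length(pitch_um) == 1) pitch_um <- rep(pitch_um, 3)
  if (length(pitch_um) != 3 || any(!is.finite(pitch_um)) || any(pitch_um <= 0))
    stop("`pitch_um` must be a positive triple (z, y, x)")
  structure(list(data = data,
                 pitch_um = stats::setNames(as.numeric(pitch_um),
                                            c("z", "y", "x")),
                 channel = channel,
                 provenance = provenance),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  ext <- d * x$pitch_um
  cat(sprintf("voxel_grid [%s]: %d x %d x %d voxels (z,y,x), pitch %.3g/%.3g/%.3g um\n",
              x$channel, d[1], d[2], d[3],
              x$pitch_um[1], x$pitch_um[2], x$pitch_um[3]))
  cat(sprintf("  extent %.1f x %.1f x %.1f um, intensity range [%.4g, %.4g]\n",
              ext[1], ext[2], ext[3], min(x$data), max(x$data)))
  invisible(x)
}

#' Physical extent of a grid in um
#' @param grid `voxel_grid` or `binary_mask`.
#' @return named triple (z, y, x).
#' @export
extent_um <- function(grid) dim(grid$data) * grid$pitch_um

is_isotropic <- function(grid, tol = 1e-6) {
  p <- grid$pitch_um
  diff(range(p)) <= tol * mean(p)
}

#' Load a multi-page TIFF stack
#'
#' @param path TIFF file, one grayscale page per z plane.
#' @param pitch_um voxel pitch (z, y, x) in um.
#' @param channel channel label, see [voxel_grid()].
#' @return `voxel_grid` with the file's intensities unchanged.
#' @export
load_stack <- function(path, pitch_um,
                       channel = c("vessel", "cell", "collagen")) {
  if (!file.exists(path)) stop("cannot read stack: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2)
    stop("`", path, "` holds a single plane: not a 3D stack")
  if (length(dim(pages[[1]])) != 2)
    stop("`", path, "` pages are not single-channel 2D planes")
  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(nz, ny, nx))
  for (k in seq_len(nz)) arr[k, , ] <- pages[[k]]
  voxel_grid(arr, pitch_um, channel, provenance = path)
}

#' Write a grid as a multi-page 32-bit TIFF
#'
#' Intensities must lie in \[0, 1\] (the TIFF writer's contract); they are
#' stored at 32-bit precision (quantization step 2^-32).
#'
#' @param grid `voxel_grid`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  x <- grid$data
  if (min(x) < 0 || max(x) > 1)
    stop("intensities outside [0, 1] cannot be stored; rescale first")
  pages <- lapply(seq_len(dim(x)[1]), function(k) x[k, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}

#' Axial-to-lateral pitch ratio for isotropic resampling
#'
#' The stack is acquired with a coarser z step than lateral pixel size; the
#' resampling factor is their ratio (e.g. 2 / 0.439 = 4.5558..., reported to
#' two decimals by truncation as 4.55).
#'
#' @param pitch_um pitch triple (z, y, x) in um; lateral pitches must match.
#' @param truncate_digits if non-NULL, truncate (not round) the factor to
#'   this many decimals, the convention used when quoting the factor.
#' @return the factor, full precision unless truncated.
#' @export
isotropic_factor <- function(pitch_um, truncate_digits = NULL) {
  if (length(pitch_um) == 1) pitch_um <- rep(pitch_um, 3)
  stopifnot(length(pitch_um) == 3, all(pitch_um > 0))
  if (abs(pitch_um[2] - pitch_um[3]) > 1e-9 * pitch_um[2])
    stop("anisotropic in-plane pitch is not supported (y != x)")
  if (pitch_um[1] < pitch_um[2] - 1e-12)
    stop("axial pitch smaller than lateral pitch; nothing to upsample")
  f <- unname(pitch_um[1] / pitch_um[3])
  if (!is.null(truncate_digits)) f <- trunc(f * 10^truncate_digits) / 10^truncate_digits
  f
}

#' Resample a stack to isotropic resolution
#'
#' Interpolates linearly along z so the output pitch equals the lateral
#' pitch.  The number of output planes is `round(nz * factor)` (half away
#' from zero).  Linear interpolation cannot overshoot, so the intensity
#' range of the input is preserved.
#'
#' @param grid `voxel_grid` with equal y/x pitch.
#' @return isotropic `voxel_grid`.
#' @export
rescale_isotropic <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  f <- isotropic_factor(grid$pitch_um)
  if (abs(f - 1) < 1e-9) {
    grid$pitch_um[] <- grid$pitch_um[3]
    return(grid)
  }
  d <- dim(grid$data)
  nz <- d[1]
  if (nz < 2) stop("cannot interpolate a single-plane stack along z")
  n_out <- as.integer(round_half_up(nz * f))
  # output plane j (0-based) sits at z = j * lateral pitch; express in input
  # plane units and interpolate between the bracketing planes
  s <- (seq_len(n_out) - 1) / f
  s <- pmin(s, nz - 1)
  k0 <- pmin(floor(s), nz - 2)
  w <- s - k0
  out <- array(0, dim = c(n_out, d[2], d[3]))
  for (j in seq_len(n_out)) {
    a <- grid$data[k0[j] + 1, , ]
    b <- grid$data[k0[j] + 2, , ]
    out[j, , ] <- (1 - w[j]) * a + w[j] * b
  }
  voxel_grid(out, rep(grid$pitch_um[3], 3), grid$channel,
             provenance = grid$provenance)
}
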