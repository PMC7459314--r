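# Structure-tensor orientation analysis: per-block direction versors on
# ~60 um blocks, local disarray (1 - Alignment) on ~120 um super-blocks,
# and the global average.  Applied to the vessel channel the statistic is
# the capillary angular dispersion; applied to the (negative) cell channel
# it is the myocardial disarray.

#' Per-block orientation versors from the 3D structure tensor
#'
#' The volume is tiled into cubic blocks of `block_size_um`.  In each block
#' the structure tensor (sum of outer products of Gaussian-derivative
#' gradients) is eigen-decomposed; the block's versor is the unit
#' eigenvector of the smallest eigenvalue - the direction of least intensity
#' variation, i.e. the axis of elongated bright structures - canonicalized
#' to the +z hemisphere.  Blocks without enough signal or without a
#' sufficiently anisotropic tensor are marked invalid, as are edge blocks
#' covering less than half a full block.
#'
#' @param grid isotropic `voxel_grid`.
#' @param block_size_um block edge (default 60 um).
#' @param gradient_sigma_um Gaussian scale of the derivative filters
#'   (default 2 um); blocks must be at least 4x this size.
#' @param min_signal_fraction minimum fraction of foreground voxels (global
#'   Otsu of the analysed image) for a block to count (default 0.01).
#' @param anisotropy_threshold minimum `1 - lambda_small/lambda_mid`
#'   (eigenvalues sorted descending) for a valid block (default 0.1).
#' @param invert analyse the intensity-inverted image (for membrane stains
#'   that outline rather than fill the structures of interest).
#' @param min_block_coverage edge blocks covering less than this fraction of
#'   a full block volume are dropped (default 0.5).
#' @return object of class `orientation_field`: data.frame `blocks` (block
#'   grid indices, versor components vz/vy/vx, anisotropy, signal fraction,
#'   valid flag), `block_size_um`, `grid_dim`.
#' @export
block_orientations <- function(grid, block_size_um = 60,
                               gradient_sigma_um = 2,
                               min_signal_fraction = 0.01,
                               anisotropy_threshold = 0.1,
                               invert = FALSE,
                               min_block_coverage = 0.5) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is_isotropic(grid))
    stop("structure-tensor analysis needs an isotropic grid; resample first")
  if (block_size_um < 4 * gradient_sigma_um)
    stop("block_size_um must be at least 4 x gradient_sigma_um")
  pitch <- grid$pitch_um[1]
  dims <- dim(grid$data)
  b_vox <- max(2L, as.integer(round(block_size_um / pitch)))
  if (b_vox > min(dims))
    stop("block size exceeds the volume extent")

  u <- grid$data
  if (invert) u <- max(u) - u
  fg <- tryCatch(u > otsu_threshold(u), error = function(e) {
    array(FALSE, dims)  # constant volume: no signal anywhere
  })
  us <- gaussian_blur(u, gradient_sigma_um / pitch)
  g <- cpp_gradient(us, as.integer(dims), as.numeric(grid$pitch_um))

  nb <- ceiling(dims / b_vox)
  blocks <- expand.grid(iz = seq_len(nb[1]), iy = seq_len(nb[2]),
                        ix = seq_len(nb[3]))
  res <- data.frame(blocks, vz = NA_real_, vy = NA_real_, vx = NA_real_,
                    anisotropy = NA_real_, signal_fraction = NA_real_,
                    n_voxels = NA_integer_, valid = FALSE)
  full <- as.numeric(b_vox)^3
  for (r in seq_len(nrow(res))) {
    zi <- ((res$iz[r] - 1) * b_vox + 1):min(res$iz[r] * b_vox, dims[1])
    yi <- ((res$iy[r] - 1) * b_vox + 1):min(res$iy[r] * b_vox, dims[2])
    xi <- ((res$ix[r] - 1) * b_vox + 1):min(res$ix[r] * b_vox, dims[3])
    nvox <- length(zi) * length(yi) * length(xi)
    res$n_voxels[r] <- nvox
    if (nvox < min_block_coverage * full) next  # unstable edge block
    G <- cbind(as.numeric(g[[1]][zi, yi, xi]),
               as.numeric(g[[2]][zi, yi, xi]),
               as.numeric(g[[3]][zi, yi, xi]))
    res$signal_fraction[r] <- mean(fg[zi, yi, xi])
    J <- crossprod(G)
    if (sum(diag(J)) <= 0) next              # constant block, zero gradients
    ev <- eigen(J, symmetric = TRUE)
    lam <- pmax(ev$values, 0)                # descending
    if (lam[2] <= 0) next
    res$anisotropy[r] <- 1 - lam[3] / lam[2]
    v <- canonicalize_versors(ev$vectors[, 3])
    res[r, c("vz", "vy", "vx")] <- v
    res$valid[r] <- res$signal_fraction[r] >= min_signal_fraction &&
      res$anisotropy[r] >= anisotropy_threshold
  }
  structure(list(blocks = res, block_size_um = block_size_um,
                 block_vox = b_vox, grid_dim = dims, pitch_um = pitch),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("orientation_field: %d blocks of %g um (%d valid)\n",
              nrow(x$blocks), x$block_size_um, sum(x$blocks$valid)))
  invisible(x)
}

#' Local disarray on super-blocks of orientation versors
#'
#' Versors are grouped into super-blocks of `super_block_um` (an integer
#' multiple of the block size; the default 120 um groups 2x2x2 = 8 blocks).
#' Per super-block, `Alignment` is the Euclidean norm of the mean of the
#' valid member versors and `Disarray = 1 - Alignment`.  Super-blocks with
#' no valid member are skipped; partial edge groups average over the valid
#' members they have.
#'
#' @param field an [block_orientations()] result.
#' @param super_block_um super-block edge, integer multiple of the field's
#'   block size.
#' @param method `"vector"` (hemisphere-canonicalized vector mean, the
#'   declared convention) or `"dyadic"` (orientation-tensor order parameter,
#'   provided as an opt-in alternative).
#' @return object of class `disarray_result`: `local_disarray` (one value
#'   per populated super-block), `global_disarray` (their mean),
#'   `n_valid_blocks`.
#' @export
local_disarray <- function(field, super_block_um = 120,
                           method = c("vector", "dyadic")) {
  stopifnot(inherits(field, "orientation_field"))
  method <- match.arg(method)
  f <- super_block_um / field$block_size_um
  if (abs(f - round(f)) > 1e-9 || round(f) < 1)
    stop("super_block_um must be an integer multiple of the block size")
  f <- as.integer(round(f))
  b <- field$blocks[field$blocks$valid, , drop = FALSE]
  if (nrow(b) == 0)
    stop("no valid orientation blocks; cannot compute disarray")
  key <- paste(ceiling(b$iz / f), ceiling(b$iy / f), ceiling(b$ix / f))
  groups <- split(seq_len(nrow(b)), key)
  local <- vapply(groups, function(idx) {
    V <- as.matrix(b[idx, c("vz", "vy", "vx")])
    if (method == "vector") {
      # sign-align the axial versors to the group's principal axis before
      # vector averaging (see versor_disarray): keeps Disarray = 1 - |mean|
      # rotation equivariant and antipodally invariant
      versor_disarray(V, canonicalize = FALSE)
    } else {
      Tm <- crossprod(V) / nrow(V)
      lam1 <- max(eigen(Tm, symmetric = TRUE, only.values = TRUE)$values)
      1 - sqrt(max(0, (3 * lam1 - 1) / 2))
    }
  }, numeric(1))
  structure(list(local_disarray = unname(local),
                 global_disarray = mean(local),
                 n_valid_blocks = nrow(b),
                 super_block_um = super_block_um,
                 method = method),
            class = "disarray_result")
}

#' @export
print.disarray_result <- function(x, ...) {
  cat(sprintf("disarray: global %.4f over %d super-blocks (%d valid blocks)\n",
              x$global_disarray, length(x$local_disarray), x$n_valid_blocks))
  invisible(x)
}

#' Global disarray: mean of the local disarrays
#'
#' @param result a `disarray_result`, or a bare numeric vector of local
#'   disarray values.
#' @return scalar in \[0, 1\].
#' @export
global_disarray <- function(result) {
  x <- if (inherits(result, "disarray_result")) result$local_disarray else result
  if (length(x) < 1) stop("no local disarray values to average")
  mean(x)
}
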