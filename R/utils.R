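# Internal numerics shared by several modules.

# Run `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.  Guarantees generator determinism without
# clobbering the session seed.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Separable Gaussian smoothing of a 3D array
#'
#' @param x 3D numeric array.
#' @param sigma_vox smoothing scale in voxels, scalar or one value per axis
#'   (axis order matching `dim(x)`); non-positive entries skip that axis.
#' @return smoothed array, same dimensions.
#' @export
gaussian_blur <- function(x, sigma_vox) {
  stopifnot(length(dim(x)) == 3)
  if (length(sigma_vox) == 1) sigma_vox <- rep(sigma_vox, 3)
  out <- cpp_gaussian_blur(as.numeric(x), as.integer(dim(x)),
                           as.numeric(sigma_vox))
  dim(out) <- dim(x)
  out
}

#' Euclidean distance transform of a binary mask
#'
#' Distance (um) from each foreground voxel to the nearest background voxel
#' centre; 0 on the background.  Voxels on a face of the volume take their
#' distance from background *inside* the volume only, so a structure clipped
#' by the stack border keeps its full radius there.
#'
#' @param mask `binary_mask` (or logical 3D array with `spacing` given).
#' @param spacing voxel pitch (um) per axis; taken from the mask when omitted.
#' @return numeric 3D array of distances in um.
#' @export
distance_transform <- function(mask, spacing = NULL) {
  if (inherits(mask, "binary_mask")) {
    spacing <- mask$pitch_um
    mask <- mask$data
  }
  stopifnot(is.logical(mask), length(dim(mask)) == 3, !is.null(spacing))
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  d <- cpp_edt(mask, as.integer(dim(mask)), as.numeric(spacing))
  dim(d) <- dim(mask)
  d
}

# Canonicalize axial unit vectors into the +z hemisphere.  Triples are in
# (z, y, x) component order package-wide: flip the sign so z > 0, breaking
# z == 0 on y > 0, then y == 0 on x > 0.
#' Map axial orientation versors to the +z hemisphere
#'
#' Orientations of fibres and tubes are "headless": v and -v are the same
#' axis.  A fixed sign convention is needed before vector averaging, else
#' alignment of perfectly parallel axes could average to zero.
#'
#' @param v numeric matrix, one unit versor per row in (z, y, x) order (a
#'   single versor may be given as a vector).
#' @return matrix of the same shape, every row in the +z hemisphere.
#' @export
canonicalize_versors <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  flip <- v[, 1] < 0 |
    (v[, 1] == 0 & v[, 2] < 0) |
    (v[, 1] == 0 & v[, 2] == 0 & v[, 3] < 0)
  v[flip, ] <- -v[flip, , drop = FALSE]
  v
}

# Sign-align axial versors to the set's principal orientation-tensor axis:
# v <- v * sign(v . ref), ref the top eigenvector of mean(v v^T).  The dyadic
# tensor ignores signs, so the result is antipodally invariant, and the
# reference co-rotates with the data, so it is rotation equivariant - unlike
# sign-fixing against a fixed pole, which splits clusters straddling the
# equator of the chosen hemisphere.  Zero dot products keep the (previously
# hemisphere-canonicalized) representative.
align_versors <- function(v) {
  ref <- eigen(crossprod(v) / nrow(v), symmetric = TRUE)$vectors[, 1]
  s <- sign(drop(v %*% ref))
  s[s == 0] <- 1
  v * s
}

#' Disarray of a set of orientation versors
#'
#' `1 - Alignment`, where Alignment is the Euclidean norm of the mean of the
#' versors after axial sign alignment (each versor's sign is chosen to agree
#' with the set's principal orientation-tensor axis; versors are axial, so v
#' and -v are the same observation).  0 for identical axes; 0.5 in the limit
#' of axes uniform on the sphere.
#'
#' @param v matrix of unit versors, one per row, (z, y, x) order.
#' @param canonicalize map to the +z hemisphere before sign alignment
#'   (default TRUE; only affects versors exactly orthogonal to the principal
#'   axis, whose representative is then the canonical one).
#' @return scalar in \[0, 1\].
#' @export
versor_disarray <- function(v, canonicalize = TRUE) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  stopifnot(ncol(v) == 3, nrow(v) >= 1)
  if (canonicalize) v <- canonicalize_versors(v)
  v <- align_versors(v)
  1 - sqrt(sum(colMeans(v)^2))
}

# round half away from zero (R's round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

# 256-bin histogram used by both automatic thresholds
intensity_histogram <- function(x, n_bins = 256L) {
  rng <- range(x, finite = TRUE)
  if (!(rng[2] > rng[1]))
    stop("volume is constant: no threshold separates two classes")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  list(counts = counts, breaks = breaks, centers = centers)
}
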