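# Per-stack scalar vascular morphometries: mean lumen diameter by the
# length-binned mean-of-modes rule, and capillary density as total vessel
# surface per stack volume, plus the automatic-vs-manual radius validation.

#' Length-bin specification for the diameter statistic
#'
#' Segments are grouped by centerline length into half-open bins
#' `[e_i, e_{i+1})`; the per-bin Mode of segment diameters is taken on a
#' fixed discretization grid.
#'
#' @param bin_edges_um strictly increasing edges, default 0,5,...,30 um;
#'   segments at or beyond the last edge are excluded.
#' @param mode_resolution_um discretization step for the Mode (default 0.1).
#' @return object of class `diameter_binning`.
#' @export
diameter_binning <- function(bin_edges_um = seq(0, 30, by = 5),
                             mode_resolution_um = 0.1) {
  stopifnot(length(bin_edges_um) >= 2, all(diff(bin_edges_um) > 0),
            mode_resolution_um > 0)
  structure(list(bin_edges_um = as.numeric(bin_edges_um),
                 mode_resolution_um = as.numeric(mode_resolution_um)),
            class = "diameter_binning")
}

# most frequent discretized value; ties resolve to the smaller diameter
discretized_mode <- function(x, resolution) {
  g <- round(x / resolution) * resolution
  tab <- table(g)
  vals <- as.numeric(names(tab))
  min(vals[tab == max(tab)])
}

#' Mean lumen diameter of a stack (mean of per-length-bin modes)
#'
#' Segments are partitioned by length into the binning's half-open bins; in
#' each non-empty bin the Mode of segment diameters (twice the mean radius,
#' discretized to `mode_resolution_um`) is computed, and the stack diameter
#' is the arithmetic mean of those modes.  Empty bins are skipped; segments
#' longer than the last edge are excluded.
#'
#' @param segments a measured `skeleton_graph`, a [segment_table()]
#'   data.frame, or any data.frame with `length_um` and `diameter_um`.
#' @param binning a [diameter_binning()].
#' @return mean diameter in um.
#' @export
mean_diameter <- function(segments, binning = diameter_binning()) {
  if (inherits(segments, "skeleton_graph")) segments <- segment_table(segments)
  stopifnot(is.data.frame(segments),
            all(c("length_um", "diameter_um") %in% names(segments)))
  e <- binning$bin_edges_um
  len <- segments$length_um
  dia <- segments$diameter_um
  keep <- !is.na(len) & !is.na(dia) & len >= e[1] & len < e[length(e)]
  if (!any(keep))
    stop("no segments fall inside the length bins [",
         e[1], ", ", e[length(e)], ") um; cannot form a diameter estimate")
  bin <- findInterval(len[keep], e)  # 1..nbins given keep
  modes <- vapply(sort(unique(bin)), function(b) {
    discretized_mode(dia[keep][bin == b], binning$mode_resolution_um)
  }, numeric(1))
  mean(modes)
}

#' Capillary density: vessel surface area per stack volume
#'
#' The numerator is the area (um^2) of the triangulated isosurface of the
#' mask at level 0.5 (marching tetrahedra on the indicator lightly smoothed
#' with a Gaussian of `smooth_sigma_vox` voxels, which suppresses the
#' voxelization staircase so the area converges to the smooth-surface
#' value); the denominator is the full physical stack volume (um^3).
#'
#' @param mask isotropic `binary_mask`.
#' @param smooth_sigma_vox pre-triangulation smoothing in voxels (default
#'   0.7; 0 triangulates the raw binary field).
#' @return density in um^-1; 0 (with a warning) for an empty mask.
#' @export
surface_density <- function(mask, smooth_sigma_vox = 0.7) {
  stopifnot(inherits(mask, "binary_mask"))
  if (diff(range(mask$pitch_um)) > 1e-6 * mean(mask$pitch_um))
    stop("surface_density needs an isotropic mask; resample first")
  vol <- prod(dim(mask$data) * mask$pitch_um)
  if (!any(mask$data)) {
    warning("empty mask: surface density is 0")
    return(0)
  }
  u <- as.numeric(mask$data)
  dim(u) <- dim(mask$data)
  if (smooth_sigma_vox > 0) u <- gaussian_blur(u, smooth_sigma_vox)
  area <- cpp_isosurface_area(u, as.integer(dim(u)), 0.5,
                              as.numeric(mask$pitch_um))
  area / vol
}

#' Skeleton length per stack volume
#'
#' Alternative "linear" density (um^-2): total centerline length divided by
#' the stack volume.  Reported alongside the surface density, clearly
#' labelled; the surface-per-volume measure is the primary density.
#'
#' @param graph `skeleton_graph`.
#' @param stack_volume_um3 physical volume of the analysed stack.
#' @return length density in um^-2.
#' @export
length_density <- function(graph, stack_volume_um3) {
  stopifnot(inherits(graph, "skeleton_graph"), stack_volume_um3 > 0)
  sum(vapply(graph$segments, `[[`, numeric(1), "length_um")) / stack_volume_um3
}

#' Automatic-vs-manual radius validation against the identity line
#'
#' Paired automatic and manual radius estimates are compared to `y = x`:
#' residual RMSE and maximum deviation from the identity line, plus the
#' through-origin regression slope (1 for perfect agreement).
#'
#' @param auto_radii,manual_radii equal-length paired measurements (n >= 2).
#' @return list of class `radius_validation`: `n`, `rmse`, `max_deviation`,
#'   `slope`.
#' @export
validate_auto_vs_manual <- function(auto_radii, manual_radii) {
  if (length(auto_radii) != length(manual_radii))
    stop("paired lists must have equal length")
  n <- length(auto_radii)
  stopifnot(n >= 2)
  resid <- auto_radii - manual_radii
  structure(list(n = n,
                 rmse = sqrt(mean(resid^2)),
                 max_deviation = max(abs(resid)),
                 slope = sum(auto_radii * manual_radii) / sum(manual_radii^2)),
            class = "radius_validation")
}

#' @export
print.radius_validation <- function(x, ...) {
  cat(sprintf("auto-vs-manual radius validation (n = %d): slope %.3f, RMSE %.3f um, max dev %.3f um\n",
              x$n, x$slope, x$rmse, x$max_deviation))
  invisible(x)
}
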