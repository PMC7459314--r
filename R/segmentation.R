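# Vessel segmentation: global Otsu threshold, binarization, 3D
# topology-preserving skeletonization and branch decomposition into measured
# centerline segments.

#' Binary 3D mask
#'
#' @param data logical 3D array, (z, y, x) order.
#' @param pitch_um voxel pitch (um), scalar or triple.
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(data, pitch_um) {
  stopifnot(is.logical(data), length(dim(data)) == 3)
  if (length(pitch_um) == 1) pitch_um <- rep(pitch_um, 3)
  stopifnot(all(pitch_um > 0))
  structure(list(data = data,
                 pitch_um = stats::setNames(as.numeric(pitch_um),
                                            c("z", "y", "x"))),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("binary_mask: %d x %d x %d voxels, %.2f%% foreground\n",
              d[1], d[2], d[3], 100 * mean(x$data)))
  invisible(x)
}

#' Otsu's global threshold
#'
#' Maximizes between-class variance over a 256-bin histogram of the whole
#' volume.  Ties resolve to the lowest qualifying threshold.
#'
#' @param grid `voxel_grid` (or bare numeric array).
#' @param n_bins histogram bins (256, the standard choice).
#' @return threshold intensity; foreground is strictly greater.
#' @export
otsu_threshold <- function(grid, n_bins = 256L) {
  x <- if (inherits(grid, "voxel_grid")) grid$data else grid
  h <- intensity_histogram(x, n_bins)
  p <- h$counts / sum(h$counts)
  omega <- cumsum(p)
  mu <- cumsum(p * h$centers)
  mu_t <- mu[n_bins]
  k <- seq_len(n_bins - 1)
  num <- (mu_t * omega[k] - mu[k])^2
  den <- omega[k] * (1 - omega[k])
  sb2 <- ifelse(den > 0, num / den, -Inf)
  best <- which.max(sb2)  # first maximum = smallest threshold on ties
  h$breaks[best + 1]
}

#' Binarize a grid at a threshold
#'
#' @param grid `voxel_grid`.
#' @param threshold foreground is intensity strictly greater than this.
#' @return `binary_mask` with the grid's pitch.
#' @export
binarize <- function(grid, threshold) {
  stopifnot(inherits(grid, "voxel_grid"))
  binary_mask(grid$data > threshold, grid$pitch_um)
}

#' Remove small connected components
#'
#' 26-connected foreground components below `min_voxels` are dropped (noise
#' suppression ahead of skeletonization).
#'
#' @param mask `binary_mask`.
#' @param min_voxels minimum component size kept (default 10).
#' @return filtered `binary_mask`.
#' @export
filter_small_components <- function(mask, min_voxels = 10L) {
  stopifnot(inherits(mask, "binary_mask"))
  out <- cpp_filter_small(mask$data, as.integer(dim(mask$data)),
                          as.integer(min_voxels))
  dim(out) <- dim(mask$data)
  binary_mask(out, mask$pitch_um)
}

#' Skeletonize a vessel mask into a segment graph
#'
#' Thins the mask to a one-voxel-wide, topology-preserving centerline
#' (distance-ordered homotopic thinning: simple points are deleted in order
#' of the Euclidean distance transform; curve endpoints are preserved), then
#' decomposes the skeleton at junction voxels (more than two 26-neighbours)
#' into maximal branch-free segments.  Junction voxels belong to the node,
#' not to any segment, so branch lengths are not double-counted.
#'
#' Thinning leaves short dangling twigs where surface bumps of the mask
#' spawn premature endpoints; terminal branches (one junction end, one free
#' end) shorter than `prune_spurs_um` are therefore removed and the graph
#' rebuilt, so branches interrupted by a pruned spur merge back together.
#' Whole components (segments with no junction end) are never pruned.
#'
#' @param mask isotropic `binary_mask` with at least one foreground voxel.
#' @param min_component_voxels connected components smaller than this are
#'   removed first (default 10).
#' @param prune_spurs_um terminal branches shorter than this are treated as
#'   thinning artifacts (default 5 um, about the capillary radius scale;
#'   0 disables pruning).
#' @return object of class `skeleton_graph`: `segments` (list; each has
#'   `polyline` in um, `length_um`, and after [measure_segments()] also
#'   `mean_radius_um` / `volume_um3`), `nodes` (data.frame of node centroids
#'   with degree), `skeleton` (logical array), `pitch_um`.
#' @export
skeletonize <- function(mask, min_component_voxels = 10L,
                        prune_spurs_um = 5) {
  stopifnot(inherits(mask, "binary_mask"))
  if (diff(range(mask$pitch_um)) > 1e-6 * mean(mask$pitch_um))
    stop("skeletonization needs an isotropic mask; resample first")
  if (!any(mask$data)) stop("mask has no foreground voxels")
  if (min_component_voxels > 1)
    mask <- filter_small_components(mask, min_component_voxels)
  if (!any(mask$data))
    stop("mask has no foreground voxels after small-component filtering")
  dims <- dim(mask$data)
  d <- cpp_edt(mask$data, as.integer(dims), as.numeric(mask$pitch_um))
  skel <- cpp_skeletonize(mask$data, as.integer(dims), d)
  dim(skel) <- dims
  graph <- build_skeleton_graph(skel, mask$pitch_um)
  if (prune_spurs_um > 0) {
    for (pass in 1:3) {
      spur <- vapply(graph$segments, function(s)
        s$n_junction_ends == 1 && s$length_um < prune_spurs_um, logical(1))
      if (!any(spur)) break
      for (s in graph$segments[spur]) skel[s$voxel_index] <- FALSE
      graph <- build_skeleton_graph(skel, mask$pitch_um)
    }
  }
  graph
}

# Decompose a 1-voxel-wide skeleton into segments and nodes.
build_skeleton_graph <- function(skel, pitch_um) {
  dims <- dim(skel)
  vox <- which(skel)                       # linear indices, 1-based
  coords <- arrayInd(vox, dims)            # (z, y, x) indices
  nvox <- length(vox)
  pitch <- pitch_um[1]

  # adjacency between skeleton voxels over the 26 neighbourhood offsets
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[o, ], nvox, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- nb[ok, 1] + dims[1] * (nb[ok, 2] - 1) +
      dims[1] * dims[2] * (nb[ok, 3] - 1)
    hit <- skel[lin]
    from <- which(ok)[hit]
    to <- match(lin[hit], vox)
    keep <- from < to                      # undirected, record once
    edges[[o]] <- cbind(from[keep], to[keep])
  }
  edges <- do.call(rbind, edges)

  g <- igraph::make_empty_graph(n = nvox, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  deg <- igraph::degree(g)
  junction <- deg >= 3

  # segments: connected components after junction-voxel removal
  g_seg <- igraph::delete_vertices(g, which(junction))
  seg_map <- which(!junction)              # new id -> original id
  comp <- igraph::components(g_seg)
  segments <- vector("list", comp$no)
  coords_um <- (coords - 1) * pitch
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    ordered <- order_path(g_seg, members)
    ids <- seg_map[ordered]
    poly <- coords_um[ids, , drop = FALSE]
    segments[[ci]] <- list(
      polyline = poly,
      voxel_index = vox[ids],
      length_um = polyline_length(poly),
      mean_radius_um = NA_real_,
      volume_um3 = NA_real_)
  }

  # nodes: junction clusters plus free endpoints
  nodes <- data.frame(z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
                      degree = integer(0), kind = character(0))
  node_of_voxel <- integer(nvox)           # 0 = not a node voxel
  if (any(junction)) {
    g_junc <- igraph::induced_subgraph(g, which(junction))
    jcomp <- igraph::components(g_junc)
    jmap <- which(junction)
    for (ci in seq_len(jcomp$no)) {
      members <- jmap[jcomp$membership == ci]
      node_of_voxel[members] <- nrow(nodes) + 1L
      ctr <- colMeans(coords_um[members, , drop = FALSE])
      nodes <- rbind(nodes, data.frame(z_um = ctr[1], y_um = ctr[2],
                                       x_um = ctr[3], degree = 0L,
                                       kind = "junction"))
    }
  }
  # attach segments to nodes; node degree = number of incident segment ends
  for (si in seq_along(segments)) {
    ends <- segments[[si]]$voxel_index[c(1, length(segments[[si]]$voxel_index))]
    incident <- integer(0)
    n_junction_ends <- 0L
    for (e in unique(ends)) {
      vi <- match(e, vox)
      nbrs <- as.integer(igraph::neighbors(g, vi))
      hit <- unique(node_of_voxel[nbrs][node_of_voxel[nbrs] > 0])
      if (length(hit) > 0) n_junction_ends <- n_junction_ends + 1L
      incident <- c(incident, hit)
    }
    segments[[si]]$node_ids <- unique(incident)
    segments[[si]]$n_junction_ends <- n_junction_ends
    for (ni in incident) nodes$degree[ni] <- nodes$degree[ni] + 1L
  }
  # free endpoints (degree <= 1 skeleton voxels) as end nodes
  free_ends <- which(deg <= 1)
  if (length(free_ends) > 0) {
    nodes <- rbind(nodes, data.frame(
      z_um = coords_um[free_ends, 1], y_um = coords_um[free_ends, 2],
      x_um = coords_um[free_ends, 3], degree = pmax(deg[free_ends], 0L),
      kind = "endpoint"))
  }

  structure(list(segments = segments, nodes = nodes, skeleton = skel,
                 pitch_um = pitch_um), class = "skeleton_graph")
}

# Order the vertices of a path (or cycle) component of g_sub; `members` are
# vertex ids within g_sub.
order_path <- function(g_sub, members) {
  if (length(members) == 1) return(members)
  sub <- igraph::induced_subgraph(g_sub, members)
  d <- igraph::degree(sub)
  start <- if (any(d <= 1)) which(d <= 1)[1] else 1L
  ord <- integer(length(members))
  visited <- logical(length(members))
  cur <- start
  for (i in seq_along(members)) {
    ord[i] <- cur
    visited[cur] <- TRUE
    nxt <- as.integer(igraph::neighbors(sub, cur))
    nxt <- nxt[!visited[nxt]]
    if (length(nxt) == 0) break
    cur <- nxt[1]
  }
  members[ord[ord > 0]]
}

#' @export
print.skeleton_graph <- function(x, ...) {
  lens <- vapply(x$segments, `[[`, numeric(1), "length_um")
  cat(sprintf("skeleton_graph: %d segments (total length %.1f um), %d nodes\n",
              length(x$segments), sum(lens), nrow(x$nodes)))
  invisible(x)
}

#' Fill per-segment radius and volume measurements
#'
#' Local radius at each centerline voxel is the Euclidean distance transform
#' of the mask evaluated there (um); `mean_radius_um` averages it along the
#' polyline and `volume_um3 = sum(pi * r_i^2 * step_i)` over consecutive
#' polyline steps.  Because the thinned skeleton is quantized to the voxel
#' grid it can sit up to about half a voxel off the true medial axis, which
#' biases the point-sampled distance low; with `ridge_corrected = TRUE` (the
#' default) the local radius is the maximum of the distance transform over
#' the voxel's 26-neighbourhood, i.e. the largest inscribed sphere touching
#' the centerline voxel's surroundings.
#'
#' @param graph `skeleton_graph` from [skeletonize()].
#' @param mask the `binary_mask` the skeleton came from.
#' @param ridge_corrected take the neighbourhood maximum of the distance
#'   transform as the local radius (default TRUE).
#' @return the graph with radii and volumes filled.
#' @export
measure_segments <- function(graph, mask, ridge_corrected = TRUE) {
  stopifnot(inherits(graph, "skeleton_graph"), inherits(mask, "binary_mask"))
  d <- distance_transform(mask)
  if (ridge_corrected) {
    dmax <- cpp_neighborhood_max(as.numeric(d), as.integer(dim(d)))
    dim(dmax) <- dim(d)
  }
  for (si in seq_along(graph$segments)) {
    seg <- graph$segments[[si]]
    r <- d[seg$voxel_index]
    if (any(r <= 0))
      stop("internal inconsistency: skeleton voxel outside the mask")
    if (ridge_corrected) r <- dmax[seg$voxel_index]
    graph$segments[[si]]$mean_radius_um <- mean(r)
    np <- nrow(seg$polyline)
    vol <- 0
    if (np >= 2) {
      steps <- sqrt(rowSums((seg$polyline[-1, , drop = FALSE] -
                             seg$polyline[-np, , drop = FALSE])^2))
      vol <- sum(pi * r[-np]^2 * steps)
    }
    graph$segments[[si]]$volume_um3 <- vol
  }
  graph
}

#' Segment table of a skeleton graph
#'
#' @param graph measured `skeleton_graph`.
#' @return data.frame with one row per segment: `length_um`,
#'   `mean_radius_um`, `diameter_um`, `volume_um3`, `n_points`.
#' @export
segment_table <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  data.frame(
    segment = seq_along(graph$segments),
    length_um = vapply(graph$segments, `[[`, numeric(1), "length_um"),
    mean_radius_um = vapply(graph$segments, `[[`, numeric(1), "mean_radius_um"),
    diameter_um = 2 * vapply(graph$segments, `[[`, numeric(1), "mean_radius_um"),
    volume_um3 = vapply(graph$segments, `[[`, numeric(1), "volume_um3"),
    n_points = vapply(graph$segments, function(s) nrow(s$polyline), integer(1)))
}
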