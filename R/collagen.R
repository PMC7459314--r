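# Collagen volume fraction from the second-harmonic channel: automatic
# binarization by the iterative-intermeans (isodata) threshold, then the
# percentage of signal voxels over the whole stack.

#' Isodata (iterative intermeans) threshold
#'
#' The fixed point of `t <- (mean below t + mean above t) / 2` on a 256-bin
#' histogram - the classic default automatic threshold of image-analysis
#' suites.
#'
#' @param grid `voxel_grid` or bare numeric array with >= 2 distinct values.
#' @param n_bins histogram bins (default 256).
#' @return threshold intensity (a bin boundary); foreground is strictly
#'   greater.
#' @export
isodata_threshold <- function(grid, n_bins = 256L) {
  x <- if (inherits(grid, "voxel_grid")) grid$data else grid
  h <- intensity_histogram(x, n_bins)
  counts <- h$counts
  centers <- h$centers
  csum <- cumsum(counts)
  cmu <- cumsum(counts * centers)
  n <- sum(counts)
  total_mu <- cmu[n_bins]
  # iterate on the bin split k: below = bins 1..k, above = k+1..256
  k <- n_bins %/% 2L
  seen <- integer(0)
  for (it in 1:1000) {
    if (csum[k] == 0) { k <- k + 1L; next }
    if (csum[k] == n) { k <- k - 1L; next }
    mu0 <- cmu[k] / csum[k]
    mu1 <- (total_mu - cmu[k]) / (n - csum[k])
    t_new <- (mu0 + mu1) / 2
    k_new <- findInterval(t_new, h$breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
    if (k_new == k) break
    if (k_new %in% seen) { k <- min(k, k_new); break }  # 2-cycle guard
    seen <- c(seen, k)
    k <- k_new
  }
  h$breaks[k + 1]
}

#' Collagen percentage of a stack
#'
#' Binarizes the second-harmonic channel at the automatic threshold and
#' returns `100 * foreground voxels / total voxels`, computed over the full
#' stack volume (no tissue masking).
#'
#' @param grid `voxel_grid` of the collagen channel.
#' @param method automatic threshold: `"isodata"` (default) or `"otsu"`.
#' @param per_plane threshold each z plane independently instead of the
#'   whole stack (default FALSE; planes without contrast count as empty).
#' @return percentage in \[0, 100\].
#' @export
collagen_percentage <- function(grid, method = c("isodata", "otsu"),
                                per_plane = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"))
  method <- match.arg(method)
  thr_fun <- if (method == "isodata") isodata_threshold else otsu_threshold
  x <- grid$data
  if (!per_plane) {
    fg <- x > thr_fun(x)
    return(100 * mean(fg))
  }
  n_fg <- 0
  for (k in seq_len(dim(x)[1])) {
    plane <- x[k, , ]
    t_k <- tryCatch(thr_fun(array(plane, c(1, dim(plane)))),
                    error = function(e) NA_real_)
    if (!is.na(t_k)) n_fg <- n_fg + sum(plane > t_k)
  }
  100 * n_fg / length(x)
}
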