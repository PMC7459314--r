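# Independent brute-force oracles for the automatic thresholds: both scan
# all 255 split points of a 256-bin histogram directly, with none of the
# cumulative-sum machinery of the implementations they check.

otsu_oracle <- function(x, n_bins = 256L) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, n_bins)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  best_k <- NA; best <- -Inf
  for (k in 1:(n_bins - 1)) {
    w0 <- sum(counts[1:k]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[1:k] * centers[1:k]) / w0
    m1 <- sum(counts[(k + 1):n_bins] * centers[(k + 1):n_bins]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; best_k <- k }
  }
  breaks[best_k + 1]
}

isodata_oracle <- function(x, n_bins = 256L) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, n_bins)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  for (k in 1:(n_bins - 1)) {
    w0 <- sum(counts[1:k]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[1:k] * centers[1:k]) / w0
    m1 <- sum(counts[(k + 1):n_bins] * centers[(k + 1):n_bins]) / w1
    t <- (m0 + m1) / 2
    k_of_t <- findInterval(t, breaks, rightmost.closed = TRUE,
                           all.inside = TRUE)
    if (k_of_t == k) return(breaks[k + 1])
  }
  NA_real_
}
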