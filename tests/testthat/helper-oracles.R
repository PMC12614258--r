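# Independent oracles used to check pipeline operations. These are
# deliberately naive (dense loops, exhaustive scans) and never call the
# implementation they verify.

# Dense 2-D convolution with mirror borders, O(n^2 k^2).
naive_convolve_reflect <- function(px, kernel) {
  r <- (nrow(kernel) - 1) / 2
  n <- nrow(px); m <- ncol(px)
  reflect <- function(i, len) {
    if (i < 1) 1 - i else if (i > len) 2 * len - i + 1 else i
  }
  out <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) {
    acc <- 0
    for (a in -r:r) for (b in -r:r) {
      acc <- acc + kernel[a + r + 1, b + r + 1] *
        px[reflect(i + a, n), reflect(j + b, m)]
    }
    out[i, j] <- acc
  }
  out
}

# Exhaustive 2-cluster FCM (m = 2) objective minimization over all
# candidate center pairs taken from the histogram bin midpoints.
# For m = 2 the optimal memberships give J(c1, c2) = sum_k w_k /
# (1/d1k^2 + 1/d2k^2).
fcm_bruteforce_threshold <- function(values, bins = 256L) {
  lo <- min(values); hi <- max(values)
  breaks <- seq(lo, hi, length.out = bins + 1L)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  w <- tabulate(idx, nbins = bins)
  mids <- (breaks[-1] + breaks[-(bins + 1L)]) / 2
  keep <- w > 0
  mids <- mids[keep]; w <- w[keep]
  best <- Inf; best_pair <- c(NA, NA)
  for (i in seq_along(mids)) {
    d1 <- (mids - mids[i])^2
    for (j in seq_along(mids)) {
      if (j <= i) next
      d2 <- (mids - mids[j])^2
      harm <- 1 / (1 / pmax(d1, 1e-300) + 1 / pmax(d2, 1e-300))
      J <- sum(w * harm)
      if (J < best) {
        best <- J
        best_pair <- c(mids[i], mids[j])
      }
    }
  }
  list(threshold = mean(best_pair), centers = sort(best_pair),
       bin_width = (hi - lo) / bins)
}

# Brute-force gamma objective on a 10x finer grid, recomputed from the
# definition (sd of unclipped compensated structure over eligible px).
gamma_bruteforce <- function(structure_px, reference_px, eligible,
                             gammas) {
  p99 <- as.numeric(quantile(reference_px[!logical(length(reference_px))],
                             0.99, names = FALSE))
  N <- pmin(pmax(reference_px / p99, 1e-3), 1)
  s <- structure_px[eligible]; Ne <- N[eligible]
  obj <- vapply(gammas, function(g) stats::sd(s * Ne^(-g)), numeric(1))
  gammas[which.min(obj)]
}
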