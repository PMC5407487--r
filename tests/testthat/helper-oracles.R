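# Independent oracles: deliberately naive re-implementations used to
# validate the package's vectorized / compiled code paths.

# Circular autocorrelation by explicit O(M) loops.
oracle_autocorr <- function(s, k) {
  M <- length(s)
  sb <- mean(s)
  num <- 0
  den <- 0
  for (j in seq_len(M)) {
    num <- num + (s[j] - sb) * (s[((j - 1 + k) %% M) + 1] - sb)
    den <- den + (s[j] - sb)^2
  }
  num / den
}

# Periodicity objective by materializing the re-ordered matrix and
# summing terms explicitly.
oracle_g <- function(values, perm, lags, period, min_var = 1e-12) {
  reord <- values[, perm, drop = FALSE]
  g <- 0
  for (i in seq_len(nrow(reord))) {
    row <- unname(reord[i, ])
    if (stats::var(row) <= min_var) next
    for (k in lags)
      g <- g + (oracle_autocorr(row, k) - cos(2 * pi * k / period))^2
  }
  g
}

# Kendall-tau distance by pairwise element comparison.
oracle_kendall <- function(p, q) {
  n <- length(p)
  disc <- 0
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      if (which(q == p[u]) > which(q == p[v])) disc <- disc + 1
    }
  }
  disc / (n * (n - 1) / 2)
}

# Dihedral-invariant ordering distance by exhaustive scan over all
# 2M rotations/reflections of b.
oracle_dihedral_distance <- function(a, b) {
  M <- length(a)
  best <- Inf
  for (variant in list(b, rev(b))) {
    for (r in seq_len(M) - 1) {
      rot <- variant[((seq_len(M) + r - 1) %% M) + 1]
      best <- min(best, oracle_kendall(a, rot))
    }
  }
  best
}

# Random valid intensity matrix.
random_imatrix <- function(N, M, seed) {
  set.seed(seed)
  intensity_matrix(matrix(runif(N * M, 0.1, 5), N, M),
                   (seq_len(N) - 0.5) / N,
                   sprintf("S%03d", seq_len(M)), "test")
}

# Per-pixel extraction oracle for a rectangular ROI and a straight
# horizontal axis from (x0, y) running in +x with the given unit length:
# loop over every pixel, test containment against the rectangle bounds,
# compute its axial coordinate directly, assign to a bin, average.
oracle_extract_rect <- function(image, xlim, ylim, x0, unit, n_bins) {
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  for (r in seq_len(nrow(image))) {
    for (c in seq_len(ncol(image))) {
      px <- c - 0.5
      py <- r - 0.5
      if (px <= xlim[1] || px >= xlim[2] || py <= ylim[1] || py >= ylim[2])
        next
      coord <- (px - x0) / unit
      if (coord < 0 || coord > 1) next
      b <- min(floor(coord * n_bins), n_bins - 1) + 1
      sums[b] <- sums[b] + image[r, c]
      counts[b] <- counts[b] + 1
    }
  }
  ifelse(counts > 0, sums / counts, NA_real_)
}

# Piecewise-linear resampling oracle (interior interpolation only).
oracle_lininterp <- function(x, y, xout) {
  vapply(xout, function(xx) {
    if (xx <= x[1]) {
      sl <- (y[2] - y[1]) / (x[2] - x[1])
      return(y[1] + sl * (xx - x[1]))
    }
    n <- length(x)
    if (xx >= x[n]) {
      sl <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
      return(y[n] + sl * (xx - x[n]))
    }
    i <- max(which(x <= xx))
    y[i] + (y[i + 1] - y[i]) * (xx - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}
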