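# Shared fixtures, built in code at test time.

random_image <- function(seed, h = 8, w = 8) {
  withr::with_seed(seed, {
    rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
  })
}

uniform_image <- function(r, g, b, h = 4, w = 4) {
  rgb_image(array(rep(c(r, g, b), each = h * w), c(h, w, 3)))
}

# The recoverable concentric phantom: 4 equal-area rings, discrete pH bands.
ring_phantom <- function(seed = 1, noise_sd = 0, size = 96) {
  generate_ph_phantom(ph_phantom_config(
    size = size, profile = "stepped", n_rings = 4,
    center_ph = 8.5, edge_ph = 6.5, noise_sd = noise_sd, seed = seed
  ))
}

# Arbitrary-line calibration built from two exact points.
new_cal_for_test <- function(slope, intercept) {
  fit_calibration(data.frame(ph = c(5, 9), fi = slope * c(5, 9) + intercept))
}

# Closed-form OLS slope/intercept from the normal equations (test oracle).
ols_oracle <- function(x, y) {
  n <- length(x)
  sl <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  c(slope = sl, intercept = mean(y) - sl * mean(x))
}

# Upper-tail chi-squared probability for even df via the closed-form series
# exp(-x/2) * sum_{j=0}^{df/2-1} (x/2)^j / j!   (test oracle).
chi2_sf_series <- function(x, df) {
  stopifnot(df %% 2 == 0)
  j <- 0:(df / 2 - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# Total within-cluster sum of squares of a labelled partition.
partition_inertia <- function(X, labels) {
  sum(vapply(split(seq_len(nrow(X)), labels), function(ix) {
    ctr <- colMeans(X[ix, , drop = FALSE])
    sum(sweep(X[ix, , drop = FALSE], 2, ctr)^2)
  }, numeric(1)))
}

# Minimum inertia over every assignment of n points to at most k groups
# (exhaustive search; keep n small).
exhaustive_min_inertia <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  labels <- rep(1L, n)
  repeat {
    if (length(unique(labels)) <= k) {
      best <- min(best, partition_inertia(X, labels))
    }
    i <- 1L
    while (i <= n && labels[i] == k) {
      labels[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
    labels[i] <- labels[i] + 1L
  }
  best
}
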