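# Shared fixtures and independent oracles, all built in code.

# Small DEAP-shaped study spec: 1-s baseline + 4-s body (512 samples) keeps
# the packet tree valid (length divisible by 2^5) while staying fast.
small_spec <- function(seed = 1, ...) {
  args <- list(n_participants = 1, n_trials = 12, n_channels = 4,
               duration_s = 5, baseline_s = 1, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}

# Periodogram band-power oracle: Welch with a single full-length segment,
# trapezoidal integral over [lo, hi). Independent of the packet transform.
fft_band_power <- function(x, fs, lo, hi) {
  ps <- welch_psd(x, fs, nperseg = length(x), overlap = 0)
  i <- ps$freq >= lo & ps$freq < hi
  f <- ps$freq[i]; p <- ps$psd[i]
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

# Gaussian class-shifted feature set for selection tests: first n_informative
# columns shifted by effect size d between classes, the rest pure noise.
gaussian_features <- function(n = 400, n_features = 19, n_informative = 5,
                              d = 2, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * n_features), n, n_features,
              dimnames = list(NULL, paste0("F", seq_len(n_features))))
  for (j in seq_len(n_informative)) x[, j] <- x[, j] + d * y
  list(x = x, y = y)
}

# Brute-force k-NN oracle: full distance sort per query, same tie-breaks
# as the implementation contract (stable index order, vote tie -> nearest).
brute_knn <- function(train_x, train_y, query_x, k) {
  apply(query_x, 1, function(v) {
    d <- sqrt(colSums((t(train_x) - v)^2))
    nb <- order(d)[seq_len(k)]
    votes <- table(train_y[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) {
      if (is.numeric(train_y)) as.numeric(top) else top
    } else train_y[nb[1]]
  })
}

# Minimal hand-built participant dataset from explicit trial matrices.
manual_dataset <- function(mats, labels, pid = 1L, fs = 128) {
  trials <- lapply(seq_along(mats), function(i) {
    eeg_trial(pid, i, mats[[i]], fs = fs, baseline_samples = 0)
  })
  structure(list(participant_id = pid, trials = trials, labels = labels),
            class = "participant_dataset")
}

# Smallest distance from point s to any segment between rows of m.
min_segment_residual <- function(s, m) {
  best <- Inf
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(m))) {
      if (i == j) next
      a <- m[i, ]; b <- m[j, ]
      ab <- b - a
      u <- sum((s - a) * ab) / sum(ab^2)
      u <- min(max(u, 0), 1)
      best <- min(best, sqrt(sum((s - (a + u * ab))^2)))
    }
  }
  best
}

# Expected in-band capture fraction for a unit sinusoid drawn uniformly in
# the band: finite-window (Hann) leakage pushes part of an edge tone's
# power outside the nominal band, so the expected periodogram integral is
# capture * A^2/2, not A^2/2. Deterministic grid oracle.
expected_band_capture <- function(n, fs, lo, hi, n_grid = 41) {
  grid <- seq(lo, hi, length.out = n_grid + 1)[-(n_grid + 1)]
  t <- (0:(n - 1)) / fs
  mean(vapply(grid, function(fr) {
    fft_band_power(sin(2 * pi * fr * t + 0.7), fs, lo, hi) / 0.5
  }, numeric(1)))
}
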