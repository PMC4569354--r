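# Independent reference implementations used to check the package's
# vectorized routines, plus small shared fixtures.

# brute-force nodal strength: explicit per-node summation loop
oracle_strength <- function(w) {
  n <- nrow(w)
  s <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j != i) s[i] <- s[i] + w[i, j]
  s
}

# brute-force Onnela clustering: exhaustive triple loop over ordered pairs
oracle_onnela <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(rep(0, n))
  wh <- w / mx
  cc <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      acc <- acc + (wh[i, j] * wh[j, h] * wh[i, h])^(1 / 3)
    }
    cc[i] <- acc / (k * (k - 1))
  }
  cc
}

# all-pairs shortest paths by Floyd-Warshall on 1/w lengths
oracle_cpl <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  mean(d[row(d) != col(d)])
}

# Benjamini-Hochberg by explicit sort-and-scan
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# random symmetric weighted graph, all weights positive (connected)
random_dense_graph <- function(n, zero_frac = 0) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  v <- runif(sum(ut), 0.05, 1)
  if (zero_frac > 0) v[sample(length(v), round(zero_frac * length(v)))] <- 0
  w[ut] <- v
  w + t(w)
}

# shared small forward-model fixture, built once per test run
small_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      head <- head_model()
      sensors <- sensor_array(64, head)
      grid <- build_source_grid(head, 0.03)
      lf <- suppressWarnings(compute_leadfield(grid, sensors, head))
      cache <<- list(head = head, sensors = sensors, grid = grid, lf = lf)
    }
    cache
  }
})

# exchangeable per-subject feature maps with spatial correlation: shared
# latent field + subject noise (no group information)
null_feature_maps <- function(n_subjects, positions, scale = 0.02) {
  n <- nrow(positions)
  base <- rnorm(n)
  d <- as.matrix(stats::dist(positions))
  k <- exp(-d / scale)
  smooth <- k %*% matrix(rnorm(n * n_subjects), n) / sqrt(rowSums(k^2))
  t(smooth) + rnorm(n_subjects)
}
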