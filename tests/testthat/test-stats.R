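test_that("Mann-Whitney: exact small-sample p, identical groups, permutation match", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)   # 2/6 of rank assignments as extreme
  expect_equal(mann_whitney(c(5, 1, 3), c(3, 1, 5))$p, 1)
  # large-sample approximation against a permutation oracle
  set.seed(1)
  a <- rnorm(13, 0.8); b <- rnorm(19)
  obs <- mann_whitney(a, b)
  pooled <- c(a, b)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[1:13]) - 13 * 14 / 2
  null <- replicate(1e5, {
    idx <- sample(32, 13)
    sum(ranks[idx]) - 13 * 14 / 2
  })
  p_perm <- mean(abs(null - 13 * 19 / 2) >= abs(u_obs - 13 * 19 / 2))
  expect_lt(abs(obs$p - p_perm), 0.01)
})

test_that("BH step-up matches the worked example and a sort-and-scan oracle", {
  values <- matrix(rnorm(40), 10)  # placeholder; direct p-vector checks below
  p <- c(0.01, 0.02, 0.03, 0.5)
  adj <- stats::p.adjust(p, "BH")
  expect_equal(adj < 0.05, c(TRUE, TRUE, TRUE, FALSE))
  set.seed(2)
  for (rep in 1:200) {
    pv <- runif(sample(3:12, 1))
    expect_equal(stats::p.adjust(pv, "BH"), oracle_bh(pv), tolerance = 1e-12)
  }
})

test_that("regional FDR testing flags shifted regions and respects BH", {
  set.seed(3)
  n_reg <- 8
  x <- matrix(rnorm(32 * n_reg), 32)
  colnames(x) <- paste0("r", 1:n_reg)
  x[1:13, 1:2] <- x[1:13, 1:2] + 3    # strong shift in regions 1-2
  lab <- rep(c(TRUE, FALSE), c(13, 19))
  res <- fdr_regional(x, lab, q = 0.05)
  expect_true(all(res$significant[1:2]))
  expect_equal(res$p_adjusted, oracle_bh(res$p), tolerance = 1e-12)
  expect_equal(nrow(res), n_reg)
  # single region reduces BH to the raw threshold
  res1 <- fdr_regional(x[, 1:2], lab)
  expect_equal(res1$p_adjusted, oracle_bh(res1$p))
})

test_that("Spearman correlation: monotone extremes and permutation oracle", {
  x <- c(1, 3, 4, 7, 9, 12)
  expect_equal(spearman_corr(x, x^3)$rho, 1)
  expect_equal(spearman_corr(x, -x)$rho, -1)
  expect_error(spearman_corr(x, rep(1, 6)), "constant")
  set.seed(4)
  a <- rnorm(10); b <- 0.5 * a + rnorm(10)
  obs <- spearman_corr(a, b)
  null <- replicate(1e5, stats::cor(rank(a), rank(sample(b)), method = "pearson"))
  p_perm <- mean(abs(null) >= abs(obs$rho) - 1e-12)
  expect_lt(abs(obs$p - p_perm), 0.01)
})

test_that("demographics: chi-square without continuity correction and pooled t", {
  tab <- matrix(c(9, 4, 11, 8), 2)   # females/males x patients/controls
  res <- demographics(tab)
  # brute-force chi-square: sum (o - e)^2 / e over the four cells
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic[res$test == "sex (chi-square)"],
               sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_equal(round(res$p[res$test == "sex (chi-square)"], 3), 0.515)
  # identical proportions: statistic 0, p = 1
  res0 <- demographics(matrix(c(10, 5, 20, 10), 2))
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1)
  expect_error(demographics(matrix(c(0, 0, 11, 8), 2)), "marginal")
  # pooled t on raw ages agrees with t.test
  set.seed(5)
  age_a <- rnorm(13, 38.6, 15.8); age_b <- rnorm(19, 38.5, 13.5)
  res_t <- demographics(tab, age_a, age_b)
  tt <- t.test(age_a, age_b, var.equal = TRUE)
  expect_equal(res_t$p[res_t$test == "age (t-test)"], tt$p.value)
  # summary-statistics route reproduces the raw-data pooled t
  summ_a <- c(mean = mean(age_a), sd = sd(age_a), n = 13)
  summ_b <- c(mean = mean(age_b), sd = sd(age_b), n = 19)
  res_s <- demographics(tab, summ_a, summ_b)
  expect_equal(res_s$p[res_s$test == "age (t-test)"], tt$p.value,
               tolerance = 1e-10)
})

test_that("vectorized pooled t agrees with t.test per column", {
  set.seed(6)
  x <- matrix(rnorm(20 * 5), 20)
  lab <- rep(c(TRUE, FALSE), 10)
  tv <- megnet:::pooled_t(x, lab)
  for (j in 1:5) {
    ref <- t.test(x[lab, j], x[!lab, j], var.equal = TRUE)$statistic
    expect_equal(tv[j], unname(ref), tolerance = 1e-12)
  }
})

test_that("grid adjacency is the 6-neighborhood and clusters never jump gaps", {
  head <- head_model()
  grid <- build_source_grid(head, 0.03)
  nb <- grid_adjacency(grid$positions, 0.03)
  # neighbor distance never exceeds 1.1 spacing
  for (i in seq_along(nb)[1:20]) {
    if (!length(nb[[i]])) next
    d <- sqrt(rowSums(sweep(grid$positions[nb[[i]], , drop = FALSE], 2,
                            grid$positions[i, ])^2))
    expect_true(all(d <= 1.1 * 0.03))
  }
  # two supra-threshold nodes farther apart than the adjacency radius stay
  # separate singleton clusters
  far <- order(grid$positions[, 1])[c(1, nrow(grid$positions))]
  tvals <- rep(0, nrow(grid$positions))
  tvals[far] <- 5
  cl <- megnet:::direction_clusters(tvals, 2, nb, 1)
  expect_length(cl$clusters, 2)
  expect_equal(lengths(cl$clusters), c(1L, 1L))
})

test_that("cluster permutation test finds a planted contiguous blob", {
  head <- head_model()
  grid <- build_source_grid(head, 0.03)
  nb <- grid_adjacency(grid$positions, 0.03)
  n_nodes <- nrow(grid$positions)
  set.seed(7)
  seedn <- which.max(grid$positions[, 1])
  blob <- c(seedn, nb[[seedn]])
  for (k in nb[[seedn]]) blob <- union(blob, nb[[k]])
  x <- matrix(rnorm(32 * n_nodes), 32)
  lab <- rep(c(TRUE, FALSE), c(13, 19))
  x[lab, blob] <- x[lab, blob] + 2      # d ~ 2 on the blob
  res <- cluster_permutation_test(x, lab, nb, t_threshold = 2,
                                  n_perm = 500, alpha = 0.01, seed = 11)
  expect_true(any(res$significant))
  best <- res$members[[which(res$significant)[1]]]
  expect_gte(length(intersect(best, blob)) / length(blob), 0.5)
  # determinism
  res2 <- cluster_permutation_test(x, lab, nb, t_threshold = 2,
                                   n_perm = 500, alpha = 0.01, seed = 11)
  expect_equal(res$p, res2$p)
  expect_identical(attr(res, "null_max"), attr(res2, "null_max"))
})

test_that("power-cluster thresholds are monotone: 1.9 clusters contain 2.0 clusters", {
  head <- head_model()
  grid <- build_source_grid(head, 0.035)
  nb <- grid_adjacency(grid$positions, 0.035)
  set.seed(8)
  x <- matrix(rnorm(32 * nrow(grid$positions)), 32)
  lab <- rep(c(TRUE, FALSE), c(13, 19))
  x[lab, 1:10] <- x[lab, 1:10] + 1.2
  r19 <- power_cluster_test(x, lab, nb, t_threshold = 1.9, n_perm = 200,
                            seed = 5)
  r20 <- power_cluster_test(x, lab, nb, t_threshold = 2.0, n_perm = 200,
                            seed = 5)
  n19 <- sort(unique(unlist(r19$members[r19$direction == "A>B"])))
  n20 <- sort(unique(unlist(r20$members[r20$direction == "A>B"])))
  expect_true(all(n20 %in% n19))
})

test_that("NBS: disjoint supra-threshold edges form separate singleton components", {
  # construct group difference confined to two vertex-disjoint edges
  set.seed(9)
  n_reg <- 8
  arr <- array(abs(rnorm(32 * n_reg * n_reg, sd = 0.05)), c(32, n_reg, n_reg))
  for (s in 1:32) {
    m <- (arr[s, , ] + t(arr[s, , ])) / 2; diag(m) <- 0; arr[s, , ] <- m
  }
  lab <- rep(c(TRUE, FALSE), c(13, 19))
  arr[lab, 1, 2] <- arr[lab, 1, 2] + 1; arr[lab, 2, 1] <- arr[lab, 1, 2]
  arr[lab, 3, 4] <- arr[lab, 3, 4] + 1; arr[lab, 4, 3] <- arr[lab, 3, 4]
  res <- nbs(arr, lab, t_threshold = 3.5, n_perm = 300, seed = 13)
  up <- res[res$direction == "A>B", ]
  expect_equal(nrow(up), 2L)
  expect_equal(up$size, c(1L, 1L))
  members <- lapply(up$members, function(m) sort(as.vector(m)))
  expect_true(list(c(1L, 2L)) %in% members || any(vapply(members, identical,
                                                         logical(1), c(1L, 2L))))
  expect_true(any(vapply(members, identical, logical(1), c(3L, 4L))))
})

test_that("NBS recovers a planted dense subgraph among regions", {
  set.seed(10)
  n_reg <- 10
  arr <- array(abs(rnorm(32 * n_reg * n_reg, sd = 0.05)) + 0.1,
               c(32, n_reg, n_reg))
  for (s in 1:32) {
    m <- (arr[s, , ] + t(arr[s, , ])) / 2; diag(m) <- 0; arr[s, , ] <- m
  }
  lab <- rep(c(TRUE, FALSE), c(13, 19))
  planted <- utils::combn(5, 2)          # all edges among regions 1..5
  for (k in seq_len(ncol(planted))) {
    i <- planted[1, k]; j <- planted[2, k]
    arr[lab, i, j] <- arr[lab, i, j] + 0.12
    arr[lab, j, i] <- arr[lab, i, j]
  }
  res <- nbs(arr, lab, t_threshold = 3.5, n_perm = 500, seed = 17)
  sig <- res[res$significant & res$direction == "A>B", ]
  expect_gte(nrow(sig), 1L)
  got <- apply(sig$members[[1]], 1, function(e) paste(sort(e), collapse = "-"))
  want <- apply(planted, 2, function(e) paste(sort(e), collapse = "-"))
  expect_gte(mean(got %in% want), 0.5)
})

test_that("permutation schemes enumerate exhaustively when feasible", {
  lab <- rep(c(TRUE, FALSE), c(2, 3))
  p <- megnet:::permutation_labels(lab, n_perm = 100, seed = 1)
  expect_true(attr(p, "exhaustive"))
  expect_equal(nrow(p), choose(5, 2))
  expect_equal(anyDuplicated(apply(p, 1, paste, collapse = "")), 0L)
  lab2 <- rep(c(TRUE, FALSE), c(13, 19))
  p2 <- megnet:::permutation_labels(lab2, n_perm = 200, seed = 1)
  expect_false(attr(p2, "exhaustive"))
  expect_equal(nrow(p2), 200L)
  expect_equal(p2[1, ], lab2)   # identity included
})

test_that("tidiers expose cluster results as plain tibbles", {
  head <- head_model()
  grid <- build_source_grid(head, 0.04)
  nb <- grid_adjacency(grid$positions, 0.04)
  set.seed(11)
  x <- matrix(rnorm(12 * nrow(grid$positions)), 12)
  x[1:6, 1:4] <- x[1:6, 1:4] + 3
  res <- cluster_permutation_test(x, rep(c(TRUE, FALSE), each = 6), nb,
                                  t_threshold = 2, n_perm = 100, seed = 2)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_null(attr(td, "null_max"))
  gl <- glance(res)
  expect_equal(gl$n_clusters, nrow(res))
})
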