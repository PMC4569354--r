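toy_spectra <- function(m) {
  # wrap an observations x nodes complex matrix as source_spectra
  structure(list(coef = array(m, c(nrow(m), 1, ncol(m))),
                 nodes = seq_len(ncol(m)), band = "alpha", n_tapers = 1),
            class = "source_spectra")
}

test_that("identical signals have zero imaginary coherence", {
  set.seed(1)
  z <- complex(real = rnorm(20), imaginary = rnorm(20))
  m <- cbind(z, z * 2.5)   # identical up to real scale
  expect_equal(imaginary_coherence(m, 1, 2), 0, tolerance = 1e-12)
})

test_that("quarter-cycle lagged noiseless sinusoids give weight 1", {
  set.seed(2)
  amp <- complex(modulus = runif(30, 0.5, 2), argument = runif(30, 0, 2 * pi))
  m <- cbind(amp, amp * exp(-1i * pi / 2))
  expect_equal(imaginary_coherence(m, 1, 2), 1, tolerance = 1e-6)
})

test_that("imaginary coherence matches the direct definition on toy coefficients", {
  set.seed(3)
  m <- matrix(complex(real = rnorm(5 * 4), imaginary = rnorm(5 * 4)), 5, 4)
  # brute-force evaluation of the definition
  brute <- function(i, j) {
    sij <- mean(m[, i] * Conj(m[, j]))
    sii <- mean(Mod(m[, i])^2); sjj <- mean(Mod(m[, j])^2)
    abs(Im(sij / sqrt(sii * sjj)))
  }
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(imaginary_coherence(m, i, j), brute(i, j), tolerance = 1e-12)
  # and the full-network builder agrees entry-wise
  net <- build_high_res_network(toy_spectra(m))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(net$adjacency[i, j], brute(i, j), tolerance = 1e-12)
})

test_that("zero-power nodes raise an informative error", {
  m <- cbind(complex(real = rnorm(5)), rep(0 + 0i, 5))
  expect_error(imaginary_coherence(m, 1, 2), "zero power at node 2")
  expect_error(build_high_res_network(toy_spectra(m)), "zero power")
})

test_that("networks are symmetric, hollow, bounded and NaN-free", {
  set.seed(4)
  m <- matrix(complex(real = rnorm(40 * 6), imaginary = rnorm(40 * 6)), 40)
  net <- build_high_res_network(toy_spectra(m))
  a <- net$adjacency
  expect_equal(a, t(a))
  expect_true(all(diag(a) == 0))
  expect_true(all(a >= 0 & a <= 1))
  expect_false(anyNA(a))
})

test_that("independent sources give small weights; a planted lagged pair dominates", {
  set.seed(5)
  n_obs <- 30 * 10           # 30 epochs x ~10 tapers
  m <- matrix(complex(real = rnorm(n_obs * 3), imaginary = rnorm(n_obs * 3)),
              n_obs, 3)
  net <- build_high_res_network(toy_spectra(m))
  off <- net$adjacency[upper.tri(net$adjacency)]
  expect_lt(mean(off), 0.15)
  # plant a lagged copy: node 3 = node 1 shifted by pi/2 plus small noise
  m[, 3] <- m[, 1] * exp(-1i * pi / 2) +
    0.2 * complex(real = rnorm(n_obs), imaginary = rnorm(n_obs))
  net2 <- build_high_res_network(toy_spectra(m))
  expect_equal(max(net2$adjacency), net2$adjacency[1, 3])
  expect_gt(net2$adjacency[1, 3], max(net2$adjacency[1, 2],
                                      net2$adjacency[2, 3]))
})

test_that("weights are invariant to per-node scale and a global phase", {
  set.seed(6)
  m <- matrix(complex(real = rnorm(25 * 3), imaginary = rnorm(25 * 3)), 25)
  net1 <- build_high_res_network(toy_spectra(m))
  # positive per-node rescaling (coherence normalization)
  m2 <- m
  m2[, 1] <- m[, 1] * 3
  m2[, 2] <- m[, 2] * 0.1
  net2 <- build_high_res_network(toy_spectra(m2))
  expect_equal(net1$adjacency, net2$adjacency, tolerance = 1e-12)
  # a common phase applied to every node cancels in the cross-spectrum
  net3 <- build_high_res_network(toy_spectra(m * exp(1i * 0.9)))
  expect_equal(net1$adjacency, net3$adjacency, tolerance = 1e-12)
  # a per-node phase rotation is NOT an invariance: it re-times the node
  # and legitimately moves coupling between the real and imaginary parts
  m4 <- m
  m4[, 2] <- m[, 2] * exp(1i * pi / 2)
  net4 <- build_high_res_network(toy_spectra(m4))
  expect_false(isTRUE(all.equal(net1$adjacency, net4$adjacency)))
})

test_that("regional aggregation averages cross-region weights only", {
  adj <- matrix(0, 4, 4)
  adj[1, 3] <- 0.1; adj[1, 4] <- 0.2; adj[2, 3] <- 0.3; adj[2, 4] <- 0.4
  adj[1, 2] <- 0.9; adj[3, 4] <- 0.8   # within-region, must be ignored
  adj <- adj + t(adj)
  net <- structure(list(adjacency = adj, resolution = "high", nodes = 1:4,
                        positions = NULL, band = "alpha", subject = 1),
                   class = "connectivity_network")
  atlas <- tibble::tibble(node = 1:4, region = c("A", "A", "B", "B"))
  low <- aggregate_to_regions(net, atlas)
  expect_equal(low$adjacency["A", "B"], 0.25)
  expect_equal(diag(low$adjacency), c(A = 0, B = 0))
  # all-equal cross weights aggregate to that weight
  adj2 <- matrix(0.5, 4, 4); diag(adj2) <- 0
  net2 <- net; net2$adjacency <- adj2
  expect_equal(aggregate_to_regions(net2, atlas)$adjacency["A", "B"], 0.5)
})

test_that("regional aggregation matches a brute-force double loop", {
  set.seed(7)
  adj <- random_dense_graph(10)
  atlas <- tibble::tibble(node = 1:10,
                          region = sample(c("r1", "r2", "r3"), 10,
                                          replace = TRUE))
  net <- structure(list(adjacency = adj, resolution = "high", nodes = 1:10,
                        positions = NULL, band = "beta1", subject = 1),
                   class = "connectivity_network")
  low <- aggregate_to_regions(net, atlas)
  for (r1 in unique(atlas$region)) for (r2 in unique(atlas$region)) {
    if (r1 >= r2) next
    acc <- 0; cnt <- 0
    for (a in atlas$node[atlas$region == r1])
      for (b in atlas$node[atlas$region == r2]) {
        acc <- acc + adj[a, b]; cnt <- cnt + 1
      }
    expect_equal(low$adjacency[r1, r2], acc / cnt, tolerance = 1e-12)
  }
})

test_that("unmapped nodes are dropped and region starvation errors", {
  adj <- random_dense_graph(5)
  net <- structure(list(adjacency = adj, resolution = "high", nodes = 1:5,
                        positions = NULL, band = "alpha", subject = 1),
                   class = "connectivity_network")
  atlas <- tibble::tibble(node = 1:4, region = c("A", "A", "B", "B"))
  expect_message(low <- aggregate_to_regions(net, atlas), "unmapped")
  expect_equal(dim(low$adjacency), c(2L, 2L))
  atlas_one <- tibble::tibble(node = 1:5, region = "A")
  expect_error(aggregate_to_regions(net, atlas_one), "2 surviving regions")
})

test_that("the octant atlas partitions all grid nodes deterministically", {
  fx <- small_setup()
  atlas <- octant_atlas(fx$grid, fx$head)
  expect_equal(nrow(atlas), nrow(fx$grid$positions))
  expect_equal(anyDuplicated(atlas$node), 0L)
  expect_gte(length(unique(atlas$region)), 2L)
  expect_identical(atlas, octant_atlas(fx$grid, fx$head))
})
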