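# Shared mass-univariate permutation machinery for node-cluster, power-cluster
# and NBS tests. One engine, parameterized by the clustering rule.

# Vectorized pooled-variance two-sample t for every column of `x`,
# group A = labels TRUE. Returns t (A - B).
pooled_t <- function(x, labels) {
  na <- sum(labels); nb <- sum(!labels)
  ma <- colMeans(x[labels, , drop = FALSE])
  mb <- colMeans(x[!labels, , drop = FALSE])
  va <- colSums(sweep(x[labels, , drop = FALSE], 2, ma)^2)
  vb <- colSums(sweep(x[!labels, , drop = FALSE], 2, mb)^2)
  sp2 <- (va + vb) / (na + nb - 2)
  tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  tt[!is.finite(tt)] <- 0
  tt
}

#' Spatial adjacency of grid nodes
#'
#' Neighbor list for cluster-forming: two nodes are neighbors when their
#' Euclidean distance is at most `radius_factor` times the grid spacing
#' (default 1.1, i.e. 6-connectivity on a regular lattice).
#'
#' @param positions Nodes x 3 position matrix (meters).
#' @param spacing Grid spacing in meters.
#' @param radius_factor Multiplier on `spacing` (default 1.1).
#' @return List of integer neighbor vectors, one per node.
#' @export
grid_adjacency <- function(positions, spacing, radius_factor = 1.1) {
  n <- nrow(positions)
  r2 <- (radius_factor * spacing)^2
  lapply(seq_len(n), function(i) {
    d2 <- rowSums(sweep(positions, 2, positions[i, ])^2)
    setdiff(which(d2 <= r2), i)
  })
}

# Connected components of `active` node set under a neighbor list.
# Returns list of integer vectors (node ids).
components_of <- function(active, neighbors) {
  if (!length(active)) return(list())
  in_set <- logical(length(neighbors))
  in_set[active] <- TRUE
  seen <- logical(length(neighbors))
  comps <- list()
  for (s in active) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- neighbors[[v]]
      nb <- nb[in_set[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Cluster masses for one t-map and one direction (+1 / -1).
# Returns list(clusters = list of node sets, stats = numeric masses).
direction_clusters <- function(tvals, threshold, neighbors, direction) {
  tv <- direction * tvals
  active <- which(tv > threshold)
  comps <- components_of(active, neighbors)
  stats <- vapply(comps, function(cc) sum(tv[cc]), numeric(1))
  list(clusters = comps, stats = stats)
}

# Permutation label matrix: n_perm rows of logical group-A membership.
# Full enumeration when the number of distinct assignments fits in n_perm;
# otherwise Monte-Carlo with the identity assignment included as first row.
permutation_labels <- function(labels, n_perm, seed) {
  n <- length(labels); na <- sum(labels)
  n_distinct <- choose(n, na)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (n_distinct <= n_perm) {
    sets <- utils::combn(n, na)
    p <- matrix(FALSE, ncol(sets), n)
    for (i in seq_len(ncol(sets))) p[i, sets[, i]] <- TRUE
    attr(p, "exhaustive") <- TRUE
    return(p)
  }
  p <- matrix(FALSE, n_perm, n)
  p[1, labels] <- TRUE                      # identity permutation
  for (i in 2:n_perm) p[i, sample(n, na)] <- TRUE
  attr(p, "exhaustive") <- FALSE
  p
}

#' Cluster-based permutation test on per-node maps
#'
#' Two-sample pooled-t at every node; supra-threshold nodes are clustered
#' by spatial adjacency; the cluster statistic is the sum of member
#' t-values; family-wise significance comes from the permutation
#' distribution of the per-permutation maximum cluster statistic, kept
#' separately per direction. Labels are exhaustively enumerated when
#' feasible, otherwise Monte-Carlo permuted with the identity included (so
#' p >= 1/n_perm).
#'
#' @param values Subjects x nodes matrix of the tested map (nodal strength
#'   or source power).
#' @param labels Logical (or two-level) group vector, `TRUE`/first level =
#'   group A; the reported direction is A minus B.
#' @param neighbors Neighbor list from [grid_adjacency()].
#' @param t_threshold Cluster-forming t threshold.
#' @param n_perm Number of permutations (default 5000).
#' @param alpha Cluster significance level.
#' @param seed Mandatory seed.
#' @return A `cluster_result` tibble: one row per supra-threshold cluster
#'   with `members` (list column), `size`, `stat`, `direction`, `p`,
#'   `significant`; attribute `null_max` holds the per-direction null
#'   distributions.
#' @export
cluster_permutation_test <- function(values, labels, neighbors,
                                     t_threshold = 2.0, n_perm = 5000,
                                     alpha = 0.01, seed) {
  if (missing(seed)) stop("a permutation seed is required")
  stopifnot(t_threshold > 0, n_perm >= 100)
  labels <- as_group_logical(labels)
  perms <- permutation_labels(labels, n_perm, seed)
  obs <- pooled_t(values, labels)
  res <- list()
  null_max <- list()
  for (dir in c(1, -1)) {
    oc <- direction_clusters(obs, t_threshold, neighbors, dir)
    nm <- apply_null(perms, function(lab) {
      tv <- pooled_t(values, lab)
      dc <- direction_clusters(tv, t_threshold, neighbors, dir)
      if (length(dc$stats)) max(dc$stats) else 0
    })
    null_max[[as.character(dir)]] <- nm
    if (length(oc$stats)) {
      p <- vapply(oc$stats, function(s) mean(nm >= s), numeric(1))
      res[[length(res) + 1L]] <- tibble::tibble(
        members = oc$clusters,
        size = lengths(oc$clusters),
        stat = dir * oc$stats,       # report signed mass
        direction = if (dir > 0) "A>B" else "B>A",
        p = p, significant = p < alpha)
    }
  }
  out <- if (length(res)) dplyr::bind_rows(res) else
    tibble::tibble(members = list(), size = integer(), stat = numeric(),
                   direction = character(), p = numeric(),
                   significant = logical())
  out <- out[order(out$p), ]
  attr(out, "null_max") <- null_max
  attr(out, "t_values") <- obs
  class(out) <- c("cluster_result", class(out))
  out
}

apply_null <- function(perms, f) {
  vapply(seq_len(nrow(perms)), function(i) f(perms[i, ]), numeric(1))
}

as_group_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  lv <- unique(labels)
  if (length(lv) != 2) stop("labels must have exactly two levels")
  labels == lv[1]
}

#' Network-based statistic (NBS) on region-level networks
#'
#' Edge-wise pooled-t between groups; edges above the t threshold form a
#' graph whose connected components are the clusters; the cluster statistic
#' is the component size in edges (extent-based NBS; the summed-t variant
#' is available via `statistic = "mass"`). Family-wise p-values come from
#' the permutation distribution of the maximum component statistic, per
#' direction.
#'
#' @param networks Subjects-long list of low-resolution
#'   `connectivity_network`s (aligned region sets), or a 3D array subjects
#'   x regions x regions.
#' @param labels Group vector as in [cluster_permutation_test()].
#' @param t_threshold Edge-forming threshold (default 3.5).
#' @param n_perm Permutations (default 5000).
#' @param alpha Component significance level (default 0.05).
#' @param seed Mandatory seed.
#' @param statistic `"extent"` (edge count, default) or `"mass"` (summed t).
#' @return A `cluster_result` tibble: per component `members` (list of
#'   edges, 2-column matrix of region indices), `regions` (list of member
#'   region names), `size` (edge count), `stat`, `direction`, `p`,
#'   `significant`; attributes `null_max` and `t_matrix`.
#' @export
nbs <- function(networks, labels, t_threshold = 3.5, n_perm = 5000,
                alpha = 0.05, seed, statistic = c("extent", "mass")) {
  if (missing(seed)) stop("a permutation seed is required")
  statistic <- match.arg(statistic)
  arr <- networks_to_array(networks)
  n_reg <- dim(arr)[2]
  if (n_reg < 3) stop("NBS needs at least 3 regions")
  region_names <- dimnames(arr)[[2]] %||% as.character(seq_len(n_reg))
  labels <- as_group_logical(labels)
  ut <- which(upper.tri(matrix(0, n_reg, n_reg)), arr.ind = TRUE)
  x <- t(apply(arr, 1, function(w) w[upper.tri(w)]))   # subjects x edges
  perms <- permutation_labels(labels, n_perm, seed)
  obs <- pooled_t(x, labels)

  comp_stats <- function(tv, dir) {
    act <- which(dir * tv > t_threshold)
    if (!length(act)) return(list(comps = list(), stats = numeric(0)))
    g <- igraph::graph_from_edgelist(ut[act, , drop = FALSE], directed = FALSE)
    mem <- igraph::components(g)$membership
    comps <- split(act, mem[ut[act, 1]])
    stats <- vapply(comps, function(e)
      if (statistic == "extent") length(e) else sum(dir * tv[e]), numeric(1))
    list(comps = unname(comps), stats = unname(stats))
  }

  res <- list()
  null_max <- list()
  for (dir in c(1, -1)) {
    oc <- comp_stats(obs, dir)
    nm <- apply_null(perms, function(lab) {
      cs <- comp_stats(pooled_t(x, lab), dir)
      if (length(cs$stats)) max(cs$stats) else 0
    })
    null_max[[as.character(dir)]] <- nm
    if (length(oc$stats)) {
      p <- vapply(oc$stats, function(s) mean(nm >= s), numeric(1))
      res[[length(res) + 1L]] <- tibble::tibble(
        members = lapply(oc$comps, function(e) ut[e, , drop = FALSE]),
        regions = lapply(oc$comps, function(e)
          sort(unique(region_names[as.vector(ut[e, , drop = FALSE])]))),
        size = lengths(oc$comps),
        stat = oc$stats,
        direction = if (dir > 0) "A>B" else "B>A",
        p = p, significant = p < alpha)
    }
  }
  out <- if (length(res)) dplyr::bind_rows(res) else
    tibble::tibble(members = list(), regions = list(), size = integer(),
                   stat = numeric(), direction = character(), p = numeric(),
                   significant = logical())
  out <- out[order(out$p), ]
  tmat <- matrix(0, n_reg, n_reg, dimnames = list(region_names, region_names))
  tmat[upper.tri(tmat)] <- obs
  tmat <- tmat + t(tmat)
  attr(out, "null_max") <- null_max
  attr(out, "t_matrix") <- tmat
  class(out) <- c("cluster_result", class(out))
  out
}

networks_to_array <- function(networks) {
  if (is.array(networks) && length(dim(networks)) == 3) return(networks)
  stopifnot(is.list(networks), length(networks) >= 2)
  mats <- lapply(networks, adjacency_of)
  n <- nrow(mats[[1]])
  if (!all(vapply(mats, nrow, integer(1)) == n))
    stop("networks have mismatched region sets")
  arr <- array(0, dim = c(length(mats), n, n))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  nm <- networks[[1]]$nodes
  if (!is.null(nm)) dimnames(arr) <- list(NULL, nm, nm)
  arr
}

#' Cluster-based permutation test on source power maps
#'
#' Identical machinery to [cluster_permutation_test()] with the
#' power-analysis defaults (t threshold 1.9, alpha 0.05).
#'
#' @inheritParams cluster_permutation_test
#' @export
power_cluster_test <- function(values, labels, neighbors, t_threshold = 1.9,
                               n_perm = 5000, alpha = 0.05, seed) {
  cluster_permutation_test(values, labels, neighbors,
                           t_threshold = t_threshold, n_perm = n_perm,
                           alpha = alpha, seed = seed)
}
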