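adjacency_of <- function(net) {
  if (inherits(net, "connectivity_network")) net$adjacency
  else if (is.matrix(net)) net
  else stop("expected a connectivity_network or adjacency matrix")
}

#' Nodal strength
#'
#' The strength of a node in a weighted network is the sum of all its
#' connection weights; the global strength is the mean over nodes.
#'
#' @param net A `connectivity_network` or symmetric adjacency matrix.
#' @return List with `nodal` (per-node strengths) and `global` (their mean).
#' @export
nodal_strength <- function(net) {
  w <- adjacency_of(net)
  s <- rowSums(w)
  list(nodal = s, global = mean(s))
}

#' Onnela weighted clustering coefficient
#'
#' `C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w'_ij w'_jh w'_ih)^(1/3)` with
#' weights max-normalized (`w' = w / max(w)`) and `k_i` the number of
#' nonzero-weight neighbors; `C_i = 0` when `k_i < 2`. The global value is
#' the mean over nodes.
#'
#' @param net A `connectivity_network` or symmetric adjacency matrix.
#' @return List with `nodal` and `global`.
#' @export
onnela_clustering <- function(net) {
  w <- adjacency_of(net)
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(list(nodal = rep(0, n), global = 0))
  wh <- (w / mx)^(1 / 3)
  k <- rowSums(w > 0)
  tri <- diag(wh %*% wh %*% wh)        # 2 * sum over unordered triangles
  c_i <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  list(nodal = c_i, global = mean(c_i))
}

#' Characteristic path length
#'
#' Edge length is the inverse weight (`1/w`, no edge where `w = 0`; the
#' `-log(w)` mapping is available as an alternative); shortest paths by
#' Dijkstra; the characteristic path length is the mean over all ordered
#' node pairs. Disconnected networks are an error: the dense coherence
#' networks this package builds are always connected, so disconnection
#' signals a broken input.
#'
#' @param net A `connectivity_network` or symmetric adjacency matrix.
#' @param length_map `"inverse"` (default) or `"neglog"`.
#' @return Scalar characteristic path length.
#' @export
char_path_length <- function(net, length_map = c("inverse", "neglog")) {
  length_map <- match.arg(length_map)
  w <- adjacency_of(net)
  n <- nrow(w)
  lens <- w
  pos <- w > 0
  lens[!pos] <- 0
  lens[pos] <- if (length_map == "inverse") 1 / w[pos] else -log(w[pos])
  g <- igraph::graph_from_adjacency_matrix(lens, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  off <- d[row(d) != col(d)]
  if (any(!is.finite(off))) stop("network is disconnected: path length undefined")
  mean(off)
}

# permute off-diagonal upper-triangle weights, symmetrize
shuffle_weights <- function(w) {
  ut <- upper.tri(w)
  v <- w[ut]
  w2 <- matrix(0, nrow(w), ncol(w))
  w2[ut] <- sample(v)
  w2 + t(w2)
}

#' Surrogate-normalized global graph measures
#'
#' Generates surrogate networks by randomly shuffling the connection
#' weights between node pairs (the full weight-permutation null, which
#' preserves the weight distribution but not the degree sequence), computes
#' global clustering and characteristic path length for each, and
#' normalizes the observed values by the surrogate means. A
#' degree-preserving alternative is not implemented; the weight-shuffle
#' null is the documented default.
#'
#' @param net A `connectivity_network` or adjacency matrix.
#' @param n_surrogates Number of surrogates (default 100).
#' @param seed Mandatory seed.
#' @param max_retries Resampling attempts for a disconnected surrogate
#'   (default 10, then error).
#' @return List: `normalized_clustering`, `normalized_path_length`,
#'   `surrogate_clustering` and `surrogate_path_length` (per-surrogate
#'   vectors), `n_surrogates`.
#' @export
surrogate_normalize <- function(net, n_surrogates = 100, seed, max_retries = 10) {
  if (missing(seed)) stop("a seed is required for surrogate generation")
  stopifnot(n_surrogates >= 1)
  w <- adjacency_of(net)
  obs_c <- onnela_clustering(w)$global
  obs_l <- char_path_length(w)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sc <- numeric(n_surrogates)
  sl <- numeric(n_surrogates)
  for (s in seq_len(n_surrogates)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      ws <- shuffle_weights(w)
      l <- tryCatch(char_path_length(ws), error = function(e) NULL)
      if (!is.null(l)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not draw a connected surrogate network")
    sc[s] <- onnela_clustering(ws)$global
    sl[s] <- l
  }
  list(normalized_clustering = obs_c / mean(sc),
       normalized_path_length = obs_l / mean(sl),
       surrogate_clustering = sc, surrogate_path_length = sl,
       n_surrogates = n_surrogates)
}

#' All graph measures for one network
#'
#' Convenience wrapper returning a one-row tibble of every implemented
#' measure, optionally surrogate-normalized.
#'
#' @param net A `connectivity_network` or adjacency matrix.
#' @param n_surrogates Surrogates for normalization; 0 skips normalization.
#' @param seed Seed for the surrogate draw (required when
#'   `n_surrogates > 0`).
#' @return A one-row tibble: `global_strength`, `global_clustering`,
#'   `char_path_length`, and (if normalized) `normalized_clustering`,
#'   `normalized_path_length`; plus `band`, `subject`, `resolution` when
#'   the input network carries them.
#' @export
graph_measures <- function(net, n_surrogates = 0, seed = NULL) {
  s <- nodal_strength(net)
  cl <- onnela_clustering(net)
  l <- char_path_length(net)
  out <- tibble::tibble(global_strength = s$global,
                        global_clustering = cl$global,
                        char_path_length = l)
  if (n_surrogates > 0) {
    if (is.null(seed)) stop("a seed is required for surrogate normalization")
    nn <- surrogate_normalize(net, n_surrogates, seed)
    out$normalized_clustering <- nn$normalized_clustering
    out$normalized_path_length <- nn$normalized_path_length
  }
  if (inherits(net, "connectivity_network")) {
    out$band <- net$band %||% NA_character_
    out$subject <- net$subject %||% NA
    out$resolution <- net$resolution
  }
  out
}
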