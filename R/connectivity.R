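#' Imaginary part of coherency between two sources
#'
#' Coherency `C_ij = S_ij / sqrt(S_ii S_jj)` with the cross-spectrum `S`
#' averaged over epochs x tapers; the connectivity weight is `|Im(C_ij)|`,
#' which vanishes for zero-lag (volume-conduction-like) coupling and lies
#' in \[0, 1\].
#'
#' @param src A `source_spectra` object (or a complex observations x nodes
#'   matrix of Fourier coefficients).
#' @param i,j Node positions within the source-spectra arrays (1-based
#'   column indices).
#' @return The scalar weight `|Im coherency|`.
#' @export
imaginary_coherence <- function(src, i, j) {
  m <- source_coef_matrix(src)
  if (nrow(m) < 2) stop("need at least 2 observations for coherence")
  sii <- mean(Mod(m[, i])^2)
  sjj <- mean(Mod(m[, j])^2)
  if (sii == 0) stop(sprintf("zero power at node %d: coherence undefined", i))
  if (sjj == 0) stop(sprintf("zero power at node %d: coherence undefined", j))
  sij <- mean(m[, i] * Conj(m[, j]))
  abs(Im(sij / sqrt(sii * sjj)))
}

source_coef_matrix <- function(src) {
  if (inherits(src, "source_spectra")) {
    d <- dim(src$coef)
    matrix(src$coef, d[1] * d[2], d[3])
  } else if (is.matrix(src)) src
  else stop("src must be a source_spectra or a complex matrix")
}

#' Build the high-resolution (grid-level) connectivity network
#'
#' All pairwise `|Im coherency|` weights between retained source nodes.
#'
#' @param src A `source_spectra` (or complex observations x nodes matrix).
#' @param nodes Optional node ids for the columns (defaults to
#'   `src$nodes`).
#' @param positions Optional nodes x 3 matrix of node positions, carried as
#'   metadata (needed later for spatial clustering).
#' @param subject Optional subject identifier.
#' @return A `connectivity_network`: symmetric `adjacency` with zero
#'   diagonal and weights in \[0, 1\], `resolution = "high"`, `nodes`,
#'   `positions`, `band`, `subject`.
#' @export
build_high_res_network <- function(src, nodes = NULL, positions = NULL,
                                   subject = NULL) {
  m <- source_coef_matrix(src)
  if (ncol(m) < 2) stop("need at least 2 retained nodes")
  if (nrow(m) < 2) stop("need at least 2 observations")
  n_obs <- nrow(m)
  s <- crossprod(m, Conj(m)) / n_obs        # S_ij = mean x_i conj(x_j)
  p <- Re(diag(s))
  if (any(p <= 0))
    stop(sprintf("zero power at node %d: coherence undefined", which(p <= 0)[1]))
  denom <- sqrt(outer(p, p))
  adj <- abs(Im(s / denom))
  diag(adj) <- 0
  adj <- (adj + t(adj)) / 2
  band <- if (inherits(src, "source_spectra")) src$band else NULL
  if (is.null(nodes))
    nodes <- if (inherits(src, "source_spectra")) src$nodes else seq_len(ncol(m))
  structure(list(adjacency = adj, resolution = "high", nodes = nodes,
                 positions = positions, band = band, subject = subject),
            class = "connectivity_network")
}

#' Deterministic toy atlas: octant partition of a source grid
#'
#' Assigns every retained grid node to one of up to eight "regions" by the
#' sign octant of its position relative to the head center. A stand-in for
#' an anatomical region lookup when none is supplied.
#'
#' @param grid A `source_grid`.
#' @param head The `head_model` used to build it.
#' @return An `atlas_mapping` tibble with columns `node`, `region`.
#' @export
octant_atlas <- function(grid, head = head_model()) {
  p <- sweep(grid$positions, 2, head$center)
  oct <- 1L + (p[, 1] >= 0) + 2L * (p[, 2] >= 0) + 4L * (p[, 3] >= 0)
  tibble::tibble(node = seq_len(nrow(p)),
                 region = sprintf("octant_%d", oct))
}

#' Read an atlas mapping from a two-column TSV
#'
#' @param path TSV file with columns `node` (integer id) and `region`.
#' @return An `atlas_mapping` tibble.
#' @export
read_atlas <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("node", "region") %in% names(df)))
    stop("atlas TSV must have columns 'node' and 'region'")
  tibble::as_tibble(df[, c("node", "region")])
}

#' Aggregate a grid-level network to region-level (low resolution)
#'
#' The weight between two regions is the mean of all grid-level weights
#' between their member nodes; within-region connections never contribute.
#' Nodes without a mapping are dropped (with a message), as are regions
#' with no retained nodes.
#'
#' @param net A high-resolution `connectivity_network`.
#' @param atlas An atlas mapping (tibble with `node`, `region`), matching
#'   the network's node ids.
#' @return A low-resolution `connectivity_network` whose `nodes` are region
#'   labels.
#' @export
aggregate_to_regions <- function(net, atlas) {
  stopifnot(inherits(net, "connectivity_network"))
  idx <- match(net$nodes, atlas$node)
  unmapped <- which(is.na(idx))
  if (length(unmapped)) {
    message(sprintf("dropping %d unmapped node(s)", length(unmapped)))
  }
  keep <- which(!is.na(idx))
  if (length(keep) < 2) stop("fewer than 2 mapped nodes")
  adj <- net$adjacency[keep, keep, drop = FALSE]
  region <- atlas$region[idx[keep]]
  regions <- sort(unique(region))
  if (length(regions) < 2) stop("fewer than 2 surviving regions")
  mm <- outer(region, regions, `==`) * 1     # nodes x regions indicator
  sums <- t(mm) %*% adj %*% mm
  counts <- outer(colSums(mm), colSums(mm))  # cross-pair counts for r != s
  low <- sums / counts
  diag(low) <- 0
  low <- (low + t(low)) / 2
  dimnames(low) <- list(regions, regions)
  structure(list(adjacency = low, resolution = "low", nodes = regions,
                 positions = NULL, band = net$band, subject = net$subject),
            class = "connectivity_network")
}

#' @export
print.connectivity_network <- function(x, ...) {
  cat(sprintf("<connectivity_network> %s resolution, %d nodes, band %s\n",
              x$resolution, nrow(x$adjacency), x$band %||% "?"))
  invisible(x)
}

#' Write a network as a TSV edge list
#' @param net A `connectivity_network`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "connectivity_network"))
  n <- nrow(net$adjacency)
  ut <- which(upper.tri(net$adjacency), arr.ind = TRUE)
  df <- data.frame(node_a = net$nodes[ut[, 1]], node_b = net$nodes[ut[, 2]],
                   weight = net$adjacency[ut])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
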