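#' Regularize a cross-spectral density matrix
#'
#' Adds a scaled identity, `S + lambda * (trace(S)/n) * I`, so that the
#' matrix can be inverted even when it is rank deficient (fewer
#' observations than channels).
#'
#' @param csd A `csd` object (see [multitaper_csd()]) or a Hermitian matrix.
#' @param lambda Regularization fraction (default 0.05, i.e. 5%).
#' @return The regularized matrix (complex).
#' @export
regularize_csd <- function(csd, lambda = 0.05) {
  if (lambda < 0) stop("lambda must be >= 0")
  s <- if (inherits(csd, "csd")) csd$matrix else csd
  stopifnot(is.matrix(s), nrow(s) == ncol(s))
  s + lambda * (sum(Re(diag(s))) / nrow(s)) * diag(nrow(s))
}

#' Construct DICS spatial filters for every grid node
#'
#' For each node with lead field `L` (channels x 3) the vector filter is
#' `A = (L' Sinv L)^-1 L' Sinv`, computed on the real part of the
#' regularized CSD. The scalar filter takes the orientation of maximal
#' power (dominant eigenvector of the pseudo-inverse of `L' Sinv L` within
#' its numerical rank; in a spherical conductor the radial direction is
#' silent and is always truncated), normalized to unit gain:
#' `w . (L u) = 1`.
#'
#' Nodes whose lead field is numerically rank zero (e.g. the sphere center)
#' are flagged and excluded from source analyses.
#'
#' @param lf A `lead_field`.
#' @param csd A `csd` or Hermitian channels x channels matrix.
#' @param lambda Regularization fraction passed to [regularize_csd()].
#' @param rank_tol Relative eigenvalue cutoff below which a lead-field
#'   direction is treated as silent (default 1e-7).
#' @return A `spatial_filters` object: `weights` (nodes x channels, real),
#'   `orientations` (nodes x 3), `excluded` (integer node ids), `lambda`,
#'   `band` (if the CSD carried one).
#' @export
dics_filters <- function(lf, csd, lambda = 0.05, rank_tol = 1e-7) {
  stopifnot(inherits(lf, "lead_field"))
  band <- if (inherits(csd, "csd")) csd$band else NULL
  s_reg <- regularize_csd(csd, lambda)
  s_real <- Re(s_reg)
  sinv <- solve(s_real)
  n_node <- lf$n_nodes
  w <- matrix(NA_real_, n_node, lf$n_sensors)
  ori <- matrix(NA_real_, n_node, 3)
  excluded <- integer(0)
  for (k in seq_len(n_node)) {
    l <- leadfield_node(lf, k)
    g <- crossprod(l, sinv %*% l)          # 3x3, symmetric
    eg <- eigen((g + t(g)) / 2, symmetric = TRUE)
    keep <- eg$values > rank_tol * max(eg$values, 0)
    if (!any(keep) || max(eg$values) <= 0) { excluded <- c(excluded, k); next }
    # source power for orientation u is 1 / (u' G u); within the retained
    # subspace the maximal-power orientation is the retained eigenvector
    # with the smallest eigenvalue of G
    idx <- which(keep)
    u <- eg$vectors[, idx[length(idx)]]
    l_opt <- drop(l %*% u)
    denom <- drop(crossprod(l_opt, sinv %*% l_opt))
    if (!is.finite(denom) || denom <= 0) { excluded <- c(excluded, k); next }
    w[k, ] <- drop(crossprod(l_opt, sinv)) / denom
    ori[k, ] <- u
  }
  structure(list(weights = w, orientations = ori, excluded = excluded,
                 lambda = lambda, band = band),
            class = "spatial_filters")
}

#' Project sensor-level Fourier coefficients into source space
#'
#' Applies each node's spatial filter to the per-epoch, per-taper sensor
#' Fourier coefficient vectors. Excluded (degenerate) nodes are dropped.
#'
#' @param filters A `spatial_filters` object.
#' @param spectra A `band_spectra` object (see [multitaper_csd()]).
#' @return A `source_spectra` object: `coef` (complex array epochs x tapers
#'   x retained nodes), `nodes` (retained node ids), `band`.
#' @export
project_sources <- function(filters, spectra) {
  stopifnot(inherits(filters, "spatial_filters"),
            inherits(spectra, "band_spectra"))
  d <- dim(spectra$fourier)
  if (d[3] != ncol(filters$weights))
    stop("channel count mismatch between filters and spectra")
  keep <- setdiff(seq_len(nrow(filters$weights)), filters$excluded)
  w <- filters$weights[keep, , drop = FALSE]
  xf <- matrix(spectra$fourier, d[1] * d[2], d[3])
  sc <- xf %*% t(w)                       # (epochs*tapers) x nodes
  coef <- array(sc, dim = c(d[1], d[2], length(keep)))
  structure(list(coef = coef, nodes = keep, band = spectra$band,
                 n_tapers = d[2]),
            class = "source_spectra")
}

#' Source power map
#'
#' Mean squared coefficient magnitude per node over epochs x tapers.
#'
#' @param src A `source_spectra` object.
#' @return A `source_power_map`: `power` (per retained node, >= 0),
#'   `nodes`, `band`.
#' @export
source_power <- function(src) {
  stopifnot(inherits(src, "source_spectra"))
  d <- dim(src$coef)
  if (d[1] * d[2] < 1) stop("need at least one observation")
  m <- matrix(src$coef, d[1] * d[2], d[3])
  structure(list(power = colMeans(Mod(m)^2), nodes = src$nodes,
                 band = src$band),
            class = "source_power_map")
}
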