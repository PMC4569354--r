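#' Canonical frequency bands
#'
#' The six bands of interest, each given as a center frequency and a
#' spectral-smoothing halfwidth: delta 2+-2, theta 6+-2, alpha 10+-2,
#' beta1 16+-4, beta2 25+-4 and gamma 40+-5 Hz.
#'
#' @param names Optional subset of band names to return.
#' @return A tibble with columns `band`, `center` (Hz), `halfwidth` (Hz).
#' @export
frequency_bands <- function(names = NULL) {
  bands <- tibble::tibble(
    band = c("delta", "theta", "alpha", "beta1", "beta2", "gamma"),
    center = c(2, 6, 10, 16, 25, 40),
    halfwidth = c(2, 2, 2, 4, 4, 5)
  )
  if (!is.null(names)) {
    missing <- setdiff(names, bands$band)
    if (length(missing)) stop("unknown band(s): ", paste(missing, collapse = ", "))
    bands <- bands[match(names, bands$band), ]
  }
  bands
}

# Resolve a band argument (name or one-row tibble/list) to list(band, center, halfwidth)
resolve_band <- function(band) {
  if (is.character(band) && length(band) == 1) {
    b <- frequency_bands(band)
    return(list(band = b$band, center = b$center, halfwidth = b$halfwidth))
  }
  if (is.data.frame(band) && nrow(band) == 1)
    return(list(band = band$band, center = band$center, halfwidth = band$halfwidth))
  if (is.list(band) && all(c("center", "halfwidth") %in% names(band)))
    return(list(band = band$band %||% "custom",
                center = band$center, halfwidth = band$halfwidth))
  stop("band must be a band name or a list/tibble with center and halfwidth")
}

#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Computes the first K DPSS tapers for a given length and spectral
#' halfwidth, where K = floor(2 * T * W) - 1 with T the window length in
#' seconds and W the halfwidth in Hz (the usual Slepian convention of
#' dropping the poorly concentrated last taper). The tapers are the top
#' eigenvectors of the symmetric tridiagonal Slepian matrix, found by Sturm
#' bisection and inverse iteration, then orthonormalized.
#'
#' @param n_samples Window length in samples.
#' @param fs Sampling rate in Hz.
#' @param halfwidth Spectral smoothing halfwidth W in Hz.
#' @param k Number of tapers; default `floor(2 * T * W) - 1`.
#' @return `n_samples` x K matrix; columns are unit-norm, mutually
#'   orthogonal tapers ordered by spectral concentration.
#' @export
dpss_tapers <- function(n_samples, fs, halfwidth, k = NULL) {
  t_len <- n_samples / fs
  if (halfwidth * t_len < 1)
    stop("time-halfwidth product below 1: too little spectral smoothing for this window")
  if (is.null(k)) k <- floor(2 * t_len * halfwidth) - 1L
  if (k < 1) stop("taper count K must be >= 1")
  w <- halfwidth / fs                      # normalized half-bandwidth
  if (w >= 0.5) stop("halfwidth must be below the Nyquist frequency")
  n <- as.integer(n_samples)
  t_idx <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * w)
  off <- t_idx[-1] * (n - t_idx[-1]) / 2

  lam <- sturm_top_eigenvalues(diag_main, off, k)
  tapers <- matrix(0, n, k)
  for (j in seq_len(k)) {
    v <- tridiag_inverse_iteration(diag_main, off, lam[j])
    if (j > 1) {  # clustered eigenvalues: re-orthogonalize
      v <- v - tapers[, 1:(j - 1), drop = FALSE] %*%
        crossprod(tapers[, 1:(j - 1), drop = FALSE], v)
    }
    v <- v / sqrt(sum(v^2))
    # sign convention: symmetric tapers integrate positive; otherwise
    # positive initial lobe
    s <- sum(v)
    if (abs(s) > 1e-7) { if (s < 0) v <- -v }
    else if (v[which.max(abs(v[1:ceiling(n / 2)]))] < 0) v <- -v
    tapers[, j] <- v
  }
  tapers
}

# Count of eigenvalues of the symmetric tridiagonal matrix strictly below x
sturm_count <- function(d, e, x) {
  q <- d[1] - x
  cnt <- as.integer(q < 0)
  tiny <- .Machine$double.xmin
  for (i in seq_along(e)) {
    if (q == 0) q <- tiny
    q <- d[i + 1] - x - e[i]^2 / q
    if (q < 0) cnt <- cnt + 1L
  }
  cnt
}

# Top k eigenvalues (descending) by bisection on the Sturm count
sturm_top_eigenvalues <- function(d, e, k) {
  n <- length(d)
  rad <- c(abs(e[1]), abs(e[-1]) + abs(e[-length(e)]), abs(e[length(e)]))
  lo0 <- min(d - rad); hi0 <- max(d + rad)
  vapply(seq_len(k), function(j) {
    target <- n - j          # want count(x) == n - j at convergence from above
    lo <- lo0; hi <- hi0
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (sturm_count(d, e, mid) >= target + 1L) hi <- mid else lo <- mid
      if (hi - lo < 1e-10 * max(1, abs(hi))) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

# One eigenvector of the tridiagonal matrix near eigenvalue lam, by inverse
# iteration with a tridiagonal LU (Thomas) solve.
tridiag_inverse_iteration <- function(d, e, lam, n_iter = 4) {
  n <- length(d)
  shift <- lam * (1 + 1e-13) + 1e-12
  dd <- d - shift
  set_local <- sin(seq_len(n))             # deterministic start vector
  v <- set_local / sqrt(sum(set_local^2))
  for (it in seq_len(n_iter)) {
    v <- thomas_solve(dd, e, v)
    nv <- sqrt(sum(v^2))
    if (!is.finite(nv) || nv == 0) break
    v <- v / nv
  }
  v
}

# Solve (tridiag(d, e) ) x = b; d length n, e length n-1 (sym off-diagonal)
thomas_solve <- function(d, e, b) {
  n <- length(d)
  cp <- numeric(n); bp <- numeric(n)
  denom <- d[1]
  if (abs(denom) < 1e-300) denom <- 1e-300
  cp[1] <- e[1] / denom
  bp[1] <- b[1] / denom
  for (i in 2:n) {
    m <- d[i] - e[i - 1] * cp[i - 1]
    if (abs(m) < 1e-300) m <- 1e-300
    if (i < n) cp[i] <- e[i] / m
    bp[i] <- (b[i] - e[i - 1] * bp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- bp[n]
  for (i in (n - 1):1) x[i] <- bp[i] - cp[i] * x[i + 1]
  x
}

#' Multitaper Fourier coefficients and cross-spectral density for one band
#'
#' Per epoch and DPSS taper, the Fourier coefficient of every channel at the
#' band's center frequency (spectral smoothing +- halfwidth comes from the
#' taper bandwidth). The cross-spectral density matrix is the average of the
#' coefficient outer products over epochs x tapers, scaled by `1/fs`
#' (tapers are unit-norm, so this is the standard multitaper density
#' normalization).
#'
#' @param rec An `epoched_recording` (see [simulate_subject()] /
#'   [segment_epochs()]).
#' @param band Band name (see [frequency_bands()]) or a list with `center`
#'   and `halfwidth` in Hz.
#' @param tapers Optional precomputed taper matrix (to reuse across
#'   subjects); must match the epoch length.
#' @return A list with class `band_spectra`: `fourier` (complex array
#'   epochs x tapers x channels), `csd` (`csd` object: Hermitian channels x
#'   channels matrix, band, n_observations), `band`, `n_tapers`.
#' @export
multitaper_csd <- function(rec, band, tapers = NULL) {
  stopifnot(inherits(rec, "epoched_recording"))
  b <- resolve_band(band)
  fs <- rec$fs
  if (b$center >= fs / 2)
    stop(sprintf("band center %.3g Hz is at/above Nyquist (%.3g Hz)", b$center, fs / 2))
  n <- dim(rec$data)[3]
  if (is.null(tapers)) tapers <- dpss_tapers(n, fs, b$halfwidth)
  if (nrow(tapers) != n) stop("taper length does not match epoch length")
  k <- ncol(tapers)
  n_epochs <- dim(rec$data)[1]
  n_chan <- dim(rec$data)[2]
  # complex exponential at the center frequency
  ph <- exp(-2i * pi * b$center * (0:(n - 1)) / fs)
  m <- tapers * ph                       # n x k, complex
  fourier <- array(0i, dim = c(n_epochs, k, n_chan))
  for (e in seq_len(n_epochs)) {
    x <- t(rec$data[e, , , drop = TRUE])  # n x channels
    if (n_chan == 1) x <- matrix(rec$data[e, 1, ], ncol = 1)
    fourier[e, , ] <- crossprod(m, x)     # k x channels (no conjugate: m holds e^{-i w t})
  }
  xf <- matrix(fourier, n_epochs * k, n_chan)
  csd_mat <- crossprod(xf, Conj(xf)) / (n_epochs * k) / fs
  csd_mat <- (csd_mat + Conj(t(csd_mat))) / 2  # enforce exact Hermitian symmetry
  csd <- structure(list(matrix = csd_mat, band = b$band,
                        center = b$center, halfwidth = b$halfwidth,
                        n_observations = n_epochs * k),
                   class = "csd")
  structure(list(fourier = fourier, csd = csd, band = b$band,
                 center = b$center, halfwidth = b$halfwidth, n_tapers = k),
            class = "band_spectra")
}

#' Pool two multitaper estimates
#'
#' Averages the CSDs of two `band_spectra` for the same band, weighting by
#' their observation counts, and concatenates the Fourier coefficients.
#' @param a,b `band_spectra` objects for the same band and channel set.
#' @return A `band_spectra`.
#' @export
pool_spectra <- function(a, b) {
  stopifnot(inherits(a, "band_spectra"), inherits(b, "band_spectra"),
            identical(a$band, b$band))
  na <- a$csd$n_observations; nb <- b$csd$n_observations
  csd_mat <- (a$csd$matrix * na + b$csd$matrix * nb) / (na + nb)
  fourier <- array(0i, dim = c(dim(a$fourier)[1] + dim(b$fourier)[1],
                               dim(a$fourier)[2], dim(a$fourier)[3]))
  fourier[seq_len(dim(a$fourier)[1]), , ] <- a$fourier
  fourier[dim(a$fourier)[1] + seq_len(dim(b$fourier)[1]), , ] <- b$fourier
  csd <- structure(list(matrix = csd_mat, band = a$band, center = a$center,
                        halfwidth = a$halfwidth, n_observations = na + nb),
                   class = "csd")
  structure(list(fourier = fourier, csd = csd, band = a$band,
                 center = a$center, halfwidth = a$halfwidth,
                 n_tapers = a$n_tapers),
            class = "band_spectra")
}
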