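#' Simulation configuration for synthetic MEG cohorts
#'
#' Describes two resting-state cohorts whose source-space networks differ by
#' a planted, band-limited, phase-lagged connectivity increase. Sources are
#' narrow-band filtered Gaussian noise; lagged coupling between a node pair
#' is imposed by mixing in a Hilbert-phase-shifted copy of the driver
#' signal. Group 2 ("patients") gets the pair coupling multiplied by
#' `planted_group_effect`.
#'
#' @param n_subjects_per_group Integer length-2, default `c(13, 19)`
#'   (patients, controls).
#' @param n_epochs Epochs per subject (default 30).
#' @param epoch_length_s Epoch length in seconds (default 10).
#' @param fs Sampling rate in Hz (default 409.6, the analysis rate).
#' @param active_nodes Data frame / tibble with columns `node`, `band`,
#'   `amplitude` (A*m) and optionally `ox, oy, oz` (dipole orientation;
#'   default a tangential unit vector at the node).
#' @param coupled_pairs Data frame with columns `node_a`, `node_b`, `band`,
#'   `phase_lag` (radians; avoid 0 and pi if the pair is meant to survive
#'   imaginary coherence) and `coupling` in \[0, 1\].
#' @param planted_group_effect Multiplicative coupling increase applied to
#'   group 2 (default 1 = null cohorts).
#' @param sensor_noise_sd White sensor noise SD in tesla (default 5e-14).
#' @param seed Master seed (mandatory for reproducible cohorts).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_subjects_per_group = c(13, 19),
                              n_epochs = 30, epoch_length_s = 10, fs = 409.6,
                              active_nodes = NULL, coupled_pairs = NULL,
                              planted_group_effect = 1,
                              sensor_noise_sd = 5e-14, seed = 1L) {
  stopifnot(length(n_subjects_per_group) == 2, all(n_subjects_per_group >= 1),
            n_epochs >= 1, epoch_length_s > 0, fs > 0, sensor_noise_sd >= 0)
  active_nodes <- if (is.null(active_nodes)) {
    tibble::tibble(node = integer(), band = character(), amplitude = numeric())
  } else tibble::as_tibble(active_nodes)
  coupled_pairs <- if (is.null(coupled_pairs)) {
    tibble::tibble(node_a = integer(), node_b = integer(), band = character(),
                   phase_lag = numeric(), coupling = numeric())
  } else tibble::as_tibble(coupled_pairs)
  if (nrow(coupled_pairs)) {
    if (any(coupled_pairs$node_a == coupled_pairs$node_b))
      stop("coupling requested between a node and itself")
    if (any(coupled_pairs$coupling < 0 | coupled_pairs$coupling > 1))
      stop("coupling strength must lie in [0, 1]")
    lag_mod <- coupled_pairs$phase_lag %% (2 * pi)
    if (any(abs(lag_mod) < 1e-9 | abs(lag_mod - pi) < 1e-9))
      warning("phase lag of 0 or pi produces no imaginary-coherence signature")
  }
  structure(list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_epochs = as.integer(n_epochs), epoch_length_s = epoch_length_s, fs = fs,
    active_nodes = active_nodes, coupled_pairs = coupled_pairs,
    planted_group_effect = planted_group_effect,
    sensor_noise_sd = sensor_noise_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

# Analytic signal via FFT (Hilbert construction)
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Narrow-band Gaussian noise, unit variance, length n at fs, band [lo, hi].
# Generated with padding so filter transients are discarded.
narrowband_noise <- function(n, fs, center, halfwidth, order = 4) {
  lo <- max(center - halfwidth, 0.05)
  hi <- min(center + halfwidth, 0.49 * fs)
  pad <- round(2 * fs)
  x <- stats::rnorm(n + 2 * pad)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  y <- y[(pad + 1):(pad + n)]
  y / stats::sd(y)
}

# Phase-shift a narrowband signal by `lag` radians (delaying its analytic phase)
phase_shift <- function(x, lag) {
  Re(analytic_signal(x) * exp(-1i * lag))
}

default_tangential <- function(p) {
  ref <- if (abs(p[3]) < max(abs(p[1]), abs(p[2]), 1e-12)) c(0, 0, 1) else c(1, 0, 0)
  t1 <- c(p[2] * ref[3] - p[3] * ref[2],
          p[3] * ref[1] - p[1] * ref[3],
          p[1] * ref[2] - p[2] * ref[1])
  nt <- sqrt(sum(t1^2))
  if (nt < 1e-12) return(c(1, 0, 0))  # node at center: orientation arbitrary
  t1 / nt
}

# Gain vector (sensors) for one node and orientation
node_gain <- function(lf, node, orient) {
  drop(leadfield_node(lf, node) %*% orient)
}

#' Simulate one subject's epoched recording
#'
#' Source signals are band-limited oscillations (narrow-band filtered
#' Gaussian noise per band definition). For each coupled pair, the follower
#' signal is `coupling * phase_shift(driver) + sqrt(1 - coupling^2) *
#' independent noise`, so `coupling` is the target source-level coherence
#' magnitude. Group-2 subjects get `coupling * planted_group_effect`
#' (clipped to 1). Sensor data are the lead-field projection plus white
#' Gaussian channel noise, cut into epochs.
#'
#' @param config A [simulation_config()].
#' @param grid A [build_source_grid()].
#' @param lf The matching [compute_leadfield()].
#' @param group 1 or 2 (group 2 receives the planted effect).
#' @param seed Seed for this subject (defaults to `config$seed`).
#' @param sensors Optional [sensor_array()] carried in the output geometry.
#' @return An `epoched_recording`: `data` (epochs x channels x samples,
#'   tesla), `fs`, `epoch_length_s`, `geometry`, plus the per-subject `snr`
#'   (RMS signal projection / RMS noise) and the source traces used
#'   (`sources`, nodes x samples, for ground-truth checks).
#' @export
simulate_subject <- function(config, grid, lf, group = 1, seed = config$seed,
                             sensors = NULL) {
  stopifnot(inherits(config, "sim_config"), group %in% c(1, 2))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  fs <- config$fs
  n_per_epoch <- round(config$epoch_length_s * fs)
  n_total <- n_per_epoch * config$n_epochs
  n_chan <- lf$n_sensors

  act <- config$active_nodes
  cp <- config$coupled_pairs
  # ensure coupled nodes have an active_nodes entry (defaults)
  need <- setdiff(unique(c(cp$node_a, cp$node_b)), act$node)
  if (length(need)) {
    act <- dplyr::bind_rows(act, tibble::tibble(
      node = need, band = cp$band[match(need, cp$node_a)] %||% NA_character_,
      amplitude = 1e-8))
    # nodes appearing only as node_b: take the band of their pair
    idx <- is.na(act$band)
    if (any(idx)) {
      for (i in which(idx)) {
        j <- which(cp$node_a == act$node[i] | cp$node_b == act$node[i])[1]
        act$band[i] <- cp$band[j]
      }
    }
  }
  if (nrow(act) && any(act$node > nrow(grid$positions) | act$node < 1))
    stop("active node index outside the source grid")
  if (nrow(act) && is.null(act$amplitude)) act$amplitude <- 1e-8
  act$amplitude[is.na(act$amplitude)] <- 1e-8

  # generate source traces per active node
  traces <- matrix(0, nrow(act), n_total)
  if (nrow(act)) {
    for (i in seq_len(nrow(act))) {
      b <- resolve_band(act$band[i])
      traces[i, ] <- narrowband_noise(n_total, fs, b$center, b$halfwidth)
    }
    # impose lagged coupling: follower = c * shifted(driver) + sqrt(1-c^2) * own
    if (nrow(cp)) {
      eff <- if (group == 2) pmin(1, cp$coupling * config$planted_group_effect) else cp$coupling
      for (i in seq_len(nrow(cp))) {
        ia <- match(cp$node_a[i], act$node)
        ib <- match(cp$node_b[i], act$node)
        shifted <- phase_shift(traces[ia, ], cp$phase_lag[i])
        traces[ib, ] <- eff[i] * shifted + sqrt(1 - eff[i]^2) * traces[ib, ]
      }
    }
  }

  # project to sensors
  sensor_sig <- matrix(0, n_chan, n_total)
  if (nrow(act)) {
    for (i in seq_len(nrow(act))) {
      orient <- if (all(c("ox", "oy", "oz") %in% names(act)) &&
                    !is.na(act$ox[i])) c(act$ox[i], act$oy[i], act$oz[i])
                else default_tangential(grid$positions[act$node[i], ])
      g <- node_gain(lf, act$node[i], orient)
      sensor_sig <- sensor_sig + outer(g, act$amplitude[i] * traces[i, ])
    }
  }
  noise <- matrix(stats::rnorm(n_chan * n_total, sd = config$sensor_noise_sd),
                  n_chan, n_total)
  snr <- if (config$sensor_noise_sd > 0 && nrow(act))
    sqrt(mean(sensor_sig^2)) / sqrt(mean(noise^2)) else Inf
  x <- sensor_sig + noise

  data <- array(0, dim = c(config$n_epochs, n_chan, n_per_epoch))
  for (e in seq_len(config$n_epochs))
    data[e, , ] <- x[, ((e - 1) * n_per_epoch + 1):(e * n_per_epoch)]

  structure(list(
    data = data, fs = fs, epoch_length_s = config$epoch_length_s,
    geometry = sensors, group = group, snr = snr,
    sources = structure(traces, dimnames = list(NULL, NULL)),
    source_nodes = act$node
  ), class = "epoched_recording")
}

#' Generate a two-group synthetic cohort with a ground-truth manifest
#'
#' Per-subject seeds are `master seed + subject ordinal`, so any subject can
#' be regenerated in isolation. The manifest records the planted pairs, the
#' affected node set, group labels, per-subject seeds and SNRs for later
#' recovery checks.
#'
#' @param config A [simulation_config()]; group sizes must both be >= 2.
#' @param grid,lf,sensors Geometry as in [simulate_subject()].
#' @return A list of class `meg_cohort`: `recordings` (list of
#'   `epoched_recording`), `manifest` (list: `groups`, `planted_pairs`,
#'   `planted_nodes`, `seeds`, `snr`, `planted_group_effect`).
#' @export
make_cohort <- function(config, grid, lf, sensors = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$n_subjects_per_group < 2))
    stop("need at least 2 subjects per group")
  n1 <- config$n_subjects_per_group[1]
  n2 <- config$n_subjects_per_group[2]
  groups <- rep(c(2L, 1L), c(n1, n2))  # group 2 = patients (planted effect) first
  recs <- vector("list", n1 + n2)
  seeds <- config$seed + seq_len(n1 + n2)
  for (s in seq_len(n1 + n2))
    recs[[s]] <- simulate_subject(config, grid, lf, group = groups[s],
                                  seed = seeds[s], sensors = sensors)
  manifest <- list(
    groups = groups,
    planted_pairs = config$coupled_pairs,
    planted_nodes = sort(unique(c(config$coupled_pairs$node_a,
                                  config$coupled_pairs$node_b))),
    seeds = seeds,
    snr = vapply(recs, function(r) r$snr, numeric(1)),
    planted_group_effect = config$planted_group_effect,
    master_seed = config$seed
  )
  structure(list(recordings = recs, manifest = manifest), class = "meg_cohort")
}

#' @export
print.meg_cohort <- function(x, ...) {
  cat(sprintf("<meg_cohort> %d subjects (%d patients / %d controls), %d planted pair(s)\n",
              length(x$recordings), sum(x$manifest$groups == 2),
              sum(x$manifest$groups == 1), nrow(x$manifest$planted_pairs)))
  invisible(x)
}
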