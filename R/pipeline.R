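# Configuration schema: every known key with its default. Defaults encode
# the canonical analysis parameters (10 s epochs, 409.6 Hz, 0.5-70 Hz,
# lambda 5%, 1 cm grid, 100 surrogates, thresholds 2.0/3.5/1.9, 5000
# permutations, alphas 0.01/0.05).
config_schema <- function() {
  list(
    seed = 1L,
    geometry = list(n_sensors = 275L, head_radius = 0.09,
                    sensor_radius_factor = 1.2, grid_spacing = 0.01),
    simulate = list(n_subjects_per_group = c(13L, 19L), n_epochs = 30L,
                    epoch_length_s = 10, fs = 409.6,
                    active_nodes = NULL, coupled_pairs = NULL,
                    planted_group_effect = 1, sensor_noise_sd = 5e-14),
    preprocess = list(bp_low = 0.5, bp_high = 70, bp_order = 4L),
    bands = c("delta", "theta", "alpha", "beta1", "beta2", "gamma"),
    beamformer = list(lambda = 0.05),
    connectivity = list(atlas = "octant"),
    graph = list(n_surrogates = 100L),
    stats = list(t_threshold_nodes = 2.0, t_threshold_nbs = 3.5,
                 t_threshold_power = 1.9, n_perm = 5000L,
                 alpha_nodes = 0.01, alpha_nbs = 0.05, alpha_power = 0.05,
                 fdr_q = 0.05),
    stages = list(graph = TRUE, stats = TRUE)
  )
}

#' Default pipeline configuration
#'
#' The full-scale configuration with every stage parameter at its canonical
#' default. Override entries with the `...` arguments (nested lists are
#' merged key-wise; unknown keys are rejected).
#'
#' @param ... Named overrides, e.g. `stats = list(n_perm = 500)`.
#' @return A validated `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- merge_config(config_schema(), list(...))
  validate_config(cfg)
}

#' Small demonstration configuration
#'
#' A desk-scale setup (6 subjects per group, 64 sensors, 3 cm grid, two
#' bands, 10 epochs of 2 s, 500 permutations) with one planted lagged
#' coupling in the beta2 band, for end-to-end smoke runs.
#'
#' @param planted_group_effect Coupling multiplier for group 2 (default 2).
#' @param seed Master seed.
#' @param ... Further overrides as in [default_config()].
#' @return A validated `run_config`.
#' @export
demo_config <- function(planted_group_effect = 2, seed = 1L, ...) {
  demo <- list(
    seed = as.integer(seed),
    geometry = list(n_sensors = 64L, grid_spacing = 0.03),
    simulate = list(
      n_subjects_per_group = c(6L, 6L), n_epochs = 10L, epoch_length_s = 2,
      fs = 256,
      coupled_pairs = data.frame(node_a = NA_integer_, node_b = NA_integer_,
                                 band = "beta2", phase_lag = pi / 2,
                                 coupling = 0.35),
      sensor_noise_sd = 1e-14,
      planted_group_effect = planted_group_effect),
    bands = c("alpha", "beta2"),
    graph = list(n_surrogates = 20L),
    stats = list(n_perm = 500L))
  do.call(default_config, merge_config(demo, list(...), strict = FALSE))
}

merge_config <- function(base, override, path = "", strict = TRUE) {
  for (i in seq_along(override)) {
    nm <- names(override)[i]
    if (strict && !nm %in% names(base))
      stop(sprintf("unknown configuration key '%s%s'", path, nm))
    if (!is.null(base[[nm]]) &&
        is.list(base[[nm]]) && !is.data.frame(base[[nm]]) &&
        is.list(override[[i]]) && !is.data.frame(override[[i]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[i]],
                                 paste0(path, nm, "$"), strict = strict)
    } else {
      base[[nm]] <- override[[i]]
    }
  }
  base
}

validate_config <- function(cfg) {
  schema <- config_schema()
  check_keys <- function(x, ref, path = "") {
    extra <- setdiff(names(x), names(ref))
    if (length(extra))
      stop(sprintf("unknown configuration key '%s%s'", path, extra[1]))
    for (nm in intersect(names(x), names(ref)))
      if (is.list(ref[[nm]]) && !is.data.frame(ref[[nm]]) &&
          !is.null(x[[nm]]) && is.list(x[[nm]]) && !is.data.frame(x[[nm]]))
        check_keys(x[[nm]], ref[[nm]], paste0(path, nm, "$"))
  }
  check_keys(cfg, schema)
  stopifnot(cfg$geometry$head_radius > 0, cfg$geometry$grid_spacing > 0,
            cfg$beamformer$lambda >= 0, cfg$stats$n_perm >= 100)
  frequency_bands(cfg$bands)   # errors on unknown band names
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; everything omitted takes its default.
#'
#' @param path YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("active_nodes", "coupled_pairs"))
    if (!is.null(raw$simulate[[nm]]))
      raw$simulate[[nm]] <- as.data.frame(
        lapply(purrr::transpose(raw$simulate[[nm]]), unlist))
  do.call(default_config, raw)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulate -> spectral -> beamform -> connect -> graph -> stats, in
#' dependency order, entirely in memory. Identical configuration and seed
#' give identical results. If the configuration's `coupled_pairs` use `NA`
#' node ids, two well-separated interior grid nodes are substituted (and
#' recorded in the manifest).
#'
#' @param config A `run_config` (see [default_config()], [demo_config()],
#'   [read_run_config()]).
#' @return A `pipeline_result` list: `grid`, `manifest` (config hash, seeds,
#'   planted ground truth, excluded nodes, warnings), `measures` (tibble of
#'   graph measures per subject x band x resolution), `networks` (per band:
#'   list of low-res networks), `strength` / `power` (per band: subjects x
#'   nodes matrices), `stats` (per band: `global`, `node_clusters`,
#'   `power_clusters`, `nbs`, `regional`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warnings <- character(0)
  head <- head_model(radius = config$geometry$head_radius)
  sensors <- sensor_array(config$geometry$n_sensors, head,
                          config$geometry$sensor_radius_factor)
  grid <- build_source_grid(head, config$geometry$grid_spacing)
  lf <- compute_leadfield(grid, sensors, head)

  cp <- config$simulate$coupled_pairs
  if (!is.null(cp) && nrow(cp) && anyNA(cp$node_a)) {
    picks <- pick_separated_nodes(grid, 2 * nrow(cp))
    cp$node_a <- picks[seq_len(nrow(cp)) * 2 - 1]
    cp$node_b <- picks[seq_len(nrow(cp)) * 2]
    config$simulate$coupled_pairs <- cp
  }
  sim_cfg <- simulation_config(
    n_subjects_per_group = config$simulate$n_subjects_per_group,
    n_epochs = config$simulate$n_epochs,
    epoch_length_s = config$simulate$epoch_length_s,
    fs = config$simulate$fs,
    active_nodes = config$simulate$active_nodes,
    coupled_pairs = config$simulate$coupled_pairs,
    planted_group_effect = config$simulate$planted_group_effect,
    sensor_noise_sd = config$simulate$sensor_noise_sd,
    seed = config$seed)
  cohort <- make_cohort(sim_cfg, grid, lf, sensors)
  labels <- cohort$manifest$groups == 2      # TRUE = patients (group A)
  n_sub <- length(cohort$recordings)

  bands <- frequency_bands(config$bands)
  atlas <- octant_atlas(grid, head)
  n_samp <- round(config$simulate$epoch_length_s * config$simulate$fs)

  per_band <- list()
  measures <- list()
  excluded_all <- integer(0)
  for (bi in seq_len(nrow(bands))) {
    b <- bands[bi, ]
    tapers <- dpss_tapers(n_samp, config$simulate$fs, b$halfwidth)
    strength <- NULL; power <- NULL
    low_nets <- vector("list", n_sub)
    node_ids <- NULL
    for (s in seq_len(n_sub)) {
      sp <- multitaper_csd(cohort$recordings[[s]], b, tapers = tapers)
      filt <- dics_filters(lf, sp$csd, lambda = config$beamformer$lambda)
      excluded_all <- union(excluded_all, filt$excluded)
      src <- project_sources(filt, sp)
      pw <- source_power(src)
      net <- build_high_res_network(
        src, positions = grid$positions[src$nodes, , drop = FALSE],
        subject = s)
      low <- aggregate_to_regions(net, atlas)
      low_nets[[s]] <- low
      if (is.null(strength)) {
        node_ids <- src$nodes
        strength <- matrix(0, n_sub, length(src$nodes))
        power <- matrix(0, n_sub, length(src$nodes))
      }
      strength[s, ] <- nodal_strength(net)$nodal
      power[s, ] <- pw$power
      if (isTRUE(config$stages$graph)) {
        gm_high <- graph_measures(net, config$graph$n_surrogates,
                                  seed = config$seed + 1000L + s)
        gm_low <- graph_measures(low, config$graph$n_surrogates,
                                 seed = config$seed + 2000L + s)
        gm_high$subject <- s; gm_high$band <- b$band; gm_high$resolution <- "high"
        gm_low$subject <- s; gm_low$band <- b$band; gm_low$resolution <- "low"
        gm_high$group <- if (labels[s]) "patient" else "control"
        gm_low$group <- gm_high$group
        measures[[length(measures) + 1L]] <- dplyr::bind_rows(gm_high, gm_low)
      }
    }
    band_res <- list(strength = strength, power = power,
                     low_networks = low_nets, nodes = node_ids)
    if (isTRUE(config$stages$stats)) {
      pos <- grid$positions[node_ids, , drop = FALSE]
      nb <- grid_adjacency(pos, config$geometry$grid_spacing)
      st <- config$stats
      band_res$stats <- list(
        global = mann_whitney(rowMeans(strength[labels, , drop = FALSE]),
                              rowMeans(strength[!labels, , drop = FALSE])),
        node_clusters = node_cluster_permutation(
          strength, labels, nb, t_threshold = st$t_threshold_nodes,
          n_perm = st$n_perm, alpha = st$alpha_nodes,
          seed = config$seed + 10L + bi),
        power_clusters = power_cluster_test(
          power, labels, nb, t_threshold = st$t_threshold_power,
          n_perm = st$n_perm, alpha = st$alpha_power,
          seed = config$seed + 20L + bi),
        nbs = nbs(low_nets, labels, t_threshold = st$t_threshold_nbs,
                  n_perm = st$n_perm, alpha = st$alpha_nbs,
                  seed = config$seed + 30L + bi),
        regional = fdr_regional(region_strength(low_nets), labels,
                                q = st$fdr_q))
    }
    per_band[[b$band]] <- band_res
  }

  manifest <- list(
    config_hash = rlang::hash(config),
    master_seed = config$seed,
    groups = cohort$manifest$groups,
    subject_seeds = cohort$manifest$seeds,
    snr = cohort$manifest$snr,
    planted_pairs = cohort$manifest$planted_pairs,
    planted_nodes = cohort$manifest$planted_nodes,
    planted_group_effect = cohort$manifest$planted_group_effect,
    excluded_nodes = sort(excluded_all),
    n_grid_nodes = nrow(grid$positions),
    bands = config$bands,
    warnings = warnings)

  structure(list(config = config, grid = grid, atlas = atlas,
                 manifest = manifest,
                 measures = if (length(measures)) dplyr::bind_rows(measures)
                            else NULL,
                 bands = per_band),
            class = "pipeline_result")
}

# per-subject regional strength matrix from a list of low-res networks
region_strength <- function(low_nets) {
  m <- t(vapply(low_nets, function(nt) nodal_strength(nt)$nodal,
                numeric(nrow(low_nets[[1]]$adjacency))))
  colnames(m) <- low_nets[[1]]$nodes
  m
}

# k grid nodes far from each other, away from both the silent center and
# the sphere boundary
pick_separated_nodes <- function(grid, k) {
  p <- grid$positions
  ctr <- colMeans(p)
  r <- sqrt(rowSums(sweep(p, 2, ctr)^2))
  interior <- which(r >= stats::quantile(r, 0.2) & r <= stats::quantile(r, 0.7))
  picks <- interior[which.max(p[interior, 1])]
  while (length(picks) < k) {
    d <- apply(p[interior, , drop = FALSE], 1, function(q)
      min(sqrt(colSums((t(p[picks, , drop = FALSE]) - q)^2))))
    picks <- c(picks, interior[which.max(d)])
  }
  picks
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects, bands: %s, %d grid nodes (%d excluded)\n",
              length(x$manifest$groups), paste(x$manifest$bands, collapse = ", "),
              x$manifest$n_grid_nodes, length(x$manifest$excluded_nodes)))
  invisible(x)
}

#' Write a pipeline manifest as JSON
#' @param result A `pipeline_result`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  jsonlite::write_json(result$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
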