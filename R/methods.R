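# broom-style tidiers and plotting helpers for result objects

#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "null_max") <- NULL
  attr(out, "t_values") <- NULL
  attr(out, "t_matrix") <- NULL
  out
}

#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x),
                 n_significant = sum(x$significant),
                 min_p = if (nrow(x)) min(x$p) else NA_real_)
}

#' @method tidy stat_result
#' @export
tidy.stat_result <- function(x, ...) tibble::as_tibble(x)

#' Null-distribution plot for a cluster-based permutation test
#'
#' Histogram of the permutation null of the maximum cluster statistic with
#' the observed cluster statistics overlaid.
#'
#' @param object A `cluster_result`.
#' @param direction `"1"` (A>B, default) or `"-1"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, direction = "1", ...) {
  nm <- attr(object, "null_max")[[direction]]
  df <- data.frame(null_max = nm)
  obs <- object[object$direction == (if (direction == "1") "A>B" else "B>A"), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$null_max)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey40") +
    ggplot2::labs(x = "max cluster statistic under permutation",
                  y = "count") +
    ggplot2::theme_minimal()
  if (nrow(obs))
    p <- p + ggplot2::geom_vline(xintercept = abs(obs$stat),
                                 linetype = "dashed", color = "firebrick")
  p
}

#' Adjacency heatmap of a connectivity network
#'
#' @param net A `connectivity_network`.
#' @return A ggplot object.
#' @export
plot_network <- function(net) {
  stopifnot(inherits(net, "connectivity_network"))
  w <- net$adjacency
  df <- expand.grid(i = seq_len(nrow(w)), j = seq_len(ncol(w)))
  df$weight <- as.vector(w)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "|Im coh|",
                  title = sprintf("%s-resolution network (%s band)",
                                  net$resolution, net$band %||% "?")) +
    ggplot2::theme_minimal()
}

#' Source power map scatter (grid nodes colored by power)
#'
#' @param pmap A `source_power_map`.
#' @param grid The `source_grid` the map lives on.
#' @return A ggplot object (axial projection, x-y plane).
#' @export
plot_source_power <- function(pmap, grid) {
  stopifnot(inherits(pmap, "source_power_map"), inherits(grid, "source_grid"))
  pos <- grid$positions[pmap$nodes, , drop = FALSE]
  df <- data.frame(x = pos[, 1], y = pos[, 2], power = pmap$power)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$power)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (m)", y = "y (m)", color = "power",
                  title = sprintf("source power (%s band)", pmap$band %||% "?")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
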