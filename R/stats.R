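#' Mann-Whitney U test between two groups
#'
#' Two-sided rank-sum test: the exact distribution when both groups are
#' small (`min(n, m) <= 8`) and tie-free, otherwise the normal
#' approximation with mid-ranks and tie-corrected variance.
#'
#' @param a,b Numeric value vectors for the two groups (each >= 2 values).
#' @return A one-row `stat_result` tibble: `statistic` (U for group a),
#'   `p`, `method`, `direction` (`"a>b"`, `"b>a"` or `"none"`).
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (all(c(a, b) == c(a, b)[1])) {
    return(stat_row(statistic = length(a) * length(b) / 2, p = 1,
                    method = "Mann-Whitney U", direction = "none"))
  }
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = FALSE))
  dir <- if (stats::median(a) > stats::median(b)) "a>b"
         else if (stats::median(a) < stats::median(b)) "b>a" else "none"
  stat_row(statistic = unname(wt$statistic), p = wt$p.value,
           method = paste0("Mann-Whitney U (", if (exact) "exact" else
             "normal approx., tie-corrected", ")"),
           direction = dir)
}

stat_row <- function(...) {
  out <- tibble::tibble(...)
  class(out) <- c("stat_result", class(out))
  out
}

#' Cluster-based permutation test on nodal strength maps
#'
#' The topological group test on high-resolution networks: per-subject
#' nodal-strength vectors, pooled-t per node, spatial clustering of
#' supra-threshold nodes (t threshold 2.0), maximum-cluster-mass
#' permutation null, clusters significant at p < 0.01.
#'
#' @inheritParams cluster_permutation_test
#' @export
node_cluster_permutation <- function(values, labels, neighbors,
                                     t_threshold = 2.0, n_perm = 5000,
                                     alpha = 0.01, seed) {
  cluster_permutation_test(values, labels, neighbors,
                           t_threshold = t_threshold, n_perm = n_perm,
                           alpha = alpha, seed = seed)
}

#' Region-wise Mann-Whitney tests with Benjamini-Hochberg correction
#'
#' One Mann-Whitney U test per region on its nodal strength, then the BH
#' step-up procedure at level `q`.
#'
#' @param values Subjects x regions matrix (column names = region labels).
#' @param labels Group vector (first level / TRUE = group a).
#' @param q FDR level (default 0.05).
#' @return A `stat_result` tibble, one row per region: `region`,
#'   `statistic`, `p`, `p_adjusted`, `significant`, `direction`.
#' @export
fdr_regional <- function(values, labels, q = 0.05) {
  stopifnot(is.matrix(values) || is.data.frame(values))
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("need at least 2 regions")
  labels <- as_group_logical(labels)
  regions <- colnames(values) %||% as.character(seq_len(ncol(values)))
  rows <- lapply(seq_len(ncol(values)), function(j) {
    mw <- mann_whitney(values[labels, j], values[!labels, j])
    tibble::tibble(region = regions[j], statistic = mw$statistic, p = mw$p,
                   direction = mw$direction)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adjusted < q
  out <- out[, c("region", "statistic", "p", "p_adjusted", "significant",
                 "direction")]
  class(out) <- c("stat_result", class(out))
  out
}

#' Spearman rank correlation
#'
#' Rho on mid-ranks; two-sided p exactly (by permutation of ranks) for
#' tie-free n <= 9, otherwise via the t approximation.
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @return A one-row `stat_result` tibble: `rho`, `p`, `n`, `method`.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 pairs")
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    stop("constant variable: Spearman correlation undefined")
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- length(x) <= 9 && !has_ties
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = exact))
  stat_row(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
           method = paste0("Spearman (", if (exact) "exact" else
             "t approximation", ")"))
}

#' Demographic group comparisons
#'
#' Two-sample t-test on age (pooled variance by default) and a Pearson
#' chi-square test without continuity correction on the 2x2 sex table.
#' Ages can be raw vectors or `(mean, sd, n)` summaries.
#'
#' @param sex_table 2x2 matrix of counts, rows = sex (e.g. F/M), columns =
#'   groups.
#' @param age_a,age_b Raw age vectors, or length-3 `c(mean, sd, n)`
#'   summaries.
#' @param var_equal Pooled-variance t-test (default TRUE).
#' @return A `stat_result` tibble with rows `age (t-test)` and
#'   `sex (chi-square)`: `test`, `statistic`, `p`.
#' @export
demographics <- function(sex_table, age_a = NULL, age_b = NULL,
                         var_equal = TRUE) {
  stopifnot(is.matrix(sex_table), all(dim(sex_table) == 2))
  if (any(rowSums(sex_table) == 0) || any(colSums(sex_table) == 0))
    stop("sex table has a zero marginal")
  chi <- suppressWarnings(stats::chisq.test(sex_table, correct = FALSE))
  rows <- list(tibble::tibble(test = "sex (chi-square)",
                              statistic = unname(chi$statistic),
                              p = chi$p.value))
  if (!is.null(age_a) && !is.null(age_b)) {
    if (length(age_a) == 3 && length(age_b) == 3 &&
        !is.null(names(age_a)) && all(names(age_a) == c("mean", "sd", "n"))) {
      tt <- summary_t_test(age_a, age_b, var_equal)
    } else if (length(age_a) >= 2 && length(age_b) >= 2) {
      t0 <- stats::t.test(age_a, age_b, var.equal = var_equal)
      tt <- c(unname(t0$statistic), t0$p.value)
    } else stop("ages must be raw vectors (n >= 2) or c(mean, sd, n) summaries")
    rows <- c(list(tibble::tibble(test = "age (t-test)",
                                  statistic = tt[1], p = tt[2])), rows)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stat_result", class(out))
  out
}

# pooled (or Welch) two-sample t from (mean, sd, n) summaries
summary_t_test <- function(a, b, var_equal = TRUE) {
  m1 <- a["mean"]; s1 <- a["sd"]; n1 <- a["n"]
  m2 <- b["mean"]; s2 <- b["sd"]; n2 <- b["n"]
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- s1^2 / n1 + s2^2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  }
  unname(c(tt, 2 * stats::pt(-abs(tt), df)))
}
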