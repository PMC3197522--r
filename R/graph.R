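#' Voxel-by-voxel Pearson correlation matrix
#'
#' @param ts A cleaned `rsn_ts` (regressed and filtered) with at least 3
#'   timepoints and no constant voxel rows.
#' @return An `rsn_corr`: symmetric matrix `r` with unit diagonal, plus
#'   labels and `n_timepoints`.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "rsn_ts"))
  assert_that(ncol(ts$data) >= 3, "need at least 3 timepoints")
  sds <- apply(ts$data, 1, sd)
  bad <- which(sds < 1e-14)
  if (length(bad) > 0)
    stop_rsn(paste("constant voxel series for voxel id(s):",
                   paste(ts$voxel_ids[bad], collapse = ", ")))
  r <- cor(t(ts$data))
  diag(r) <- 1
  structure(
    list(network = ts$network, subject_id = ts$subject_id, r = r,
         voxel_ids = ts$voxel_ids, n_timepoints = ncol(ts$data)),
    class = "rsn_corr"
  )
}

#' Threshold a correlation matrix into an undirected binary graph
#'
#' An edge joins voxels i and j iff `r[i, j] > T` (signed r by default; set
#' `absolute = TRUE` to threshold `|r|`). All grid thresholds are positive
#' and target positive coupling, matching the rationale of excluding weak,
#' potentially non-significant connections.
#'
#' @param corr An `rsn_corr` or a plain symmetric correlation matrix.
#' @param threshold T in (0, 1).
#' @param absolute Threshold on `|r|` instead of signed r.
#' @return An `rsn_graph`: `n_nodes`, `edges` (m x 2 integer matrix, i < j),
#'   `threshold`.
#' @export
threshold_graph <- function(corr, threshold, absolute = FALSE) {
  r <- if (inherits(corr, "rsn_corr")) corr$r else corr
  assert_that(threshold > 0 && threshold < 1, "threshold must be in (0, 1)")
  v <- if (absolute) abs(r) else r
  idx <- which(upper.tri(v) & v > threshold, arr.ind = TRUE)
  structure(
    list(n_nodes = nrow(r),
         edges = matrix(as.integer(idx), ncol = 2,
                        dimnames = list(NULL, c("i", "j"))),
         threshold = threshold,
         network = if (inherits(corr, "rsn_corr")) corr$network else NULL,
         subject_id = if (inherits(corr, "rsn_corr")) corr$subject_id
                      else NULL),
    class = "rsn_graph"
  )
}

#' @export
print.rsn_graph <- function(x, ...) {
  cat(sprintf("<rsn_graph> N=%d, E=%d, T=%.3f\n", x$n_nodes,
              nrow(x$edges), x$threshold))
  invisible(x)
}

#' Node degrees
#' @param g An `rsn_graph`.
#' @return Integer vector of per-node degrees.
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "rsn_graph"))
  tabulate(c(g$edges[, 1], g$edges[, 2]), nbins = g$n_nodes)
}

#' Clustering coefficient
#'
#' Per node, the fraction of the node's neighbor pairs that are themselves
#' connected: `C_i = 2 e_i / (k_i (k_i - 1))` for degree `k_i >= 2`, and 0
#' for degree below 2. The network value `C` is the average over ALL nodes.
#'
#' @param g An `rsn_graph`.
#' @return List with per-node `clustering` and the mean `C`.
#' @export
clustering_coefficient <- function(g) {
  stopifnot(inherits(g, "rsn_graph"))
  ci <- cpp_local_clustering(g$edges, g$n_nodes)
  list(clustering = ci, C = mean(ci))
}

#' Characteristic path length
#'
#' Mean breadth-first-search shortest-path length over all unordered
#' connected node pairs within the largest connected component, reported
#' together with the largest-component fraction.
#'
#' @param g An `rsn_graph` with at least one edge.
#' @return List with `L`, `lcc_fraction`, `n_components`, `component`
#'   (per-node component id, 1-based).
#' @export
path_length <- function(g) {
  stopifnot(inherits(g, "rsn_graph"))
  if (nrow(g$edges) == 0) stop_rsn("no paths: graph has no edges")
  pl <- cpp_path_length(g$edges, g$n_nodes)
  list(L = pl$path_length,
       lcc_fraction = pl$lcc_size / g$n_nodes,
       n_components = pl$n_components,
       component = pl$component + 1L)
}

#' All graph metrics at once
#'
#' @param g An `rsn_graph`.
#' @return An `rsn_metrics`: `N`, `E`, `degrees`, per-node `clustering`,
#'   `C`, `L`, `lcc_fraction`.
#' @export
graph_metrics <- function(g) {
  cc <- clustering_coefficient(g)
  pl <- path_length(g)
  structure(
    list(N = g$n_nodes, E = nrow(g$edges), degrees = degrees(g),
         clustering = cc$clustering, C = cc$C, L = pl$L,
         lcc_fraction = pl$lcc_fraction,
         network = g$network, subject_id = g$subject_id,
         threshold = g$threshold),
    class = "rsn_metrics"
  )
}

#' @export
print.rsn_metrics <- function(x, ...) {
  cat(sprintf("<rsn_metrics> N=%d E=%d C=%.3f L=%.3f lcc=%.2f\n",
              x$N, x$E, x$C, x$L, x$lcc_fraction))
  invisible(x)
}

#' Glance at graph metrics
#' @param x An `rsn_metrics`.
#' @param ... Unused.
#' @return One-row tibble (subject, network, threshold, N, E, C, L,
#'   lcc_fraction).
#' @export
glance.rsn_metrics <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id %||% NA_character_,
                 network = x$network %||% NA_character_,
                 threshold = x$threshold, N = x$N, E = x$E,
                 C = x$C, L = x$L, lcc_fraction = x$lcc_fraction)
}

#' The correlation-threshold grid
#'
#' Eighteen thresholds from 0.125 to 0.55 in steps of 0.025.
#'
#' @return Numeric vector of length 18.
#' @export
threshold_grid <- function() seq(0.125, 0.55, by = 0.025)

#' Critical Pearson r for a two-sided test
#'
#' Inverts the t transform of the correlation coefficient:
#' `r = t / sqrt(df + t^2)` with `t = qt(1 - alpha/2, df)`.
#'
#' @param alpha Two-sided significance level.
#' @param df Degrees of freedom (timepoints - 2).
#' @return Critical r.
#' @export
critical_r <- function(alpha, df) {
  tcrit <- qt(1 - alpha / 2, df)
  tcrit / sqrt(df + tcrit^2)
}

#' Data-driven analysis threshold
#'
#' The smallest grid threshold at or above the critical r for
#' `alpha = 0.05 / n_pairs` (Bonferroni over the voxel pairs of the largest
#' network) at `df = n_timepoints - 2`. This is the conservative threshold
#' at which single-threshold network statistics are computed.
#'
#' @param n_voxels_max Voxel count of the largest network.
#' @param n_timepoints Number of volumes.
#' @param grid Threshold grid.
#' @return The selected threshold (one grid value).
#' @export
analysis_threshold <- function(n_voxels_max, n_timepoints,
                               grid = threshold_grid()) {
  n_pairs <- choose(n_voxels_max, 2)
  rc <- critical_r(0.05 / n_pairs, n_timepoints - 2)
  ok <- grid[grid >= rc]
  if (length(ok) == 0)
    stop_rsn("critical r exceeds the whole threshold grid")
  min(ok)
}

#' Equalize node counts across networks by random subsampling
#'
#' Every network is subsampled (uniformly, without replacement) to the
#' smallest network's node count; repeated draws let downstream metrics be
#' averaged over subsamples.
#'
#' @param voxel_sets Named list of voxel-id vectors (>= 2 networks).
#' @param n_draws Number of independent draws.
#' @param seed Integer seed.
#' @return List of length `n_draws`; each element a named list of
#'   equal-sized voxel subsets.
#' @export
equalize_nodes <- function(voxel_sets, n_draws = 10, seed = 1L) {
  assert_that(length(voxel_sets) >= 2, "need at least 2 networks")
  n_min <- min(lengths(voxel_sets))
  with_seed(seed, {
    lapply(seq_len(n_draws), function(d)
      lapply(voxel_sets, function(v) sort(sample(v, n_min))))
  })
}
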