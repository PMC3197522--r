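#' Degree-preserving rewiring (Maslov-Sneppen)
#'
#' Randomizes a graph's topology by repeated double-edge swaps
#' (a-b, c-d) -> (a-d, c-b), each accepted only if it creates no self-loop
#' or duplicate edge, so every node's degree (and the edge count) is
#' preserved exactly. The default budget of `10 * E` successful swaps is a
#' common burn-in heuristic for full randomization.
#'
#' @param g An `rsn_graph` with at least 2 edges.
#' @param n_swaps Successful swaps to perform (default `10 * E`, or
#'   `10 * E_complement` when the complement is rewired).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A rewired `rsn_graph`. If no valid swap exists (e.g. a complete
#'   graph) the input is returned unchanged with a warning.
#' @details Graphs denser than half of all possible edges are randomized
#'   by swapping edges of the complement graph instead: a double-edge swap
#'   on the complement preserves the complement's degrees, hence the
#'   original degree sequence too, and mixes far faster when few non-edges
#'   remain.
#' @export
rewire_preserving_degree <- function(g, n_swaps = NULL, seed = NULL) {
  stopifnot(inherits(g, "rsn_graph"))
  m <- nrow(g$edges)
  assert_that(m >= 2, "need at least 2 edges to rewire")
  n_pairs <- choose(g$n_nodes, 2)
  use_complement <- m > n_pairs / 2 && n_pairs - m >= 2
  edges <- if (use_complement) complement_edges(g) else g$edges
  m_eff <- nrow(edges)
  if (m_eff < 2) {  # complete or nearly complete: nothing to swap
    warning("graph admits no valid double-edge swap; returning input")
    return(g)
  }
  if (is.null(n_swaps)) n_swaps <- 10L * m_eff
  run <- function() cpp_rewire(edges, g$n_nodes, as.integer(n_swaps), 30)
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  if (res$swaps_done == 0) {
    warning("graph admits no valid double-edge swap; returning input")
    return(g)
  }
  out <- res$edges
  if (use_complement) {
    gc <- g
    gc$edges <- out
    out <- complement_edges(gc)
  }
  colnames(out) <- c("i", "j")
  g$edges <- out
  g
}

# Edge list of the complement graph (no self-loops), i < j.
complement_edges <- function(g) {
  a <- matrix(FALSE, g$n_nodes, g$n_nodes)
  a[g$edges] <- TRUE
  a[g$edges[, c(2, 1), drop = FALSE]] <- TRUE
  idx <- which(upper.tri(a) & !a, arr.ind = TRUE)
  matrix(as.integer(idx), ncol = 2, dimnames = list(NULL, c("i", "j")))
}

#' Small-world indices against a rewired null ensemble
#'
#' Generates `m` degree-matched random graphs by Maslov-Sneppen rewiring,
#' averages their clustering coefficient and path length into `c_rand` and
#' `l_rand`, and reports `gamma = C / c_rand`, `lambda = L / l_rand`,
#' `sigma = gamma / lambda`. Rewired graphs follow the same
#' largest-component rule for L as the observed graph.
#'
#' @param metrics `rsn_metrics` of the observed graph (or `NULL` to
#'   compute them here).
#' @param g The observed `rsn_graph`.
#' @param m Ensemble size (default 30).
#' @param seed Integer seed for the ensemble.
#' @param n_swaps Swap budget per draw (default `10 * E`).
#' @return An `rsn_smallworld`: `gamma`, `lambda`, `sigma`, and an
#'   `ensemble` list (`m`, `c_rand`, `l_rand`, per-draw `C` and `L`).
#' @export
small_world_indices <- function(metrics = NULL, g, m = 30, seed = 1L,
                                n_swaps = NULL) {
  stopifnot(inherits(g, "rsn_graph"))
  assert_that(m >= 1, "ensemble size m must be at least 1")
  if (is.null(metrics)) metrics <- graph_metrics(g)
  ens <- with_seed(seed, {
    lapply(seq_len(m), function(i) {
      gr <- rewire_preserving_degree(g, n_swaps = n_swaps)
      cc <- clustering_coefficient(gr)
      pl <- path_length(gr)
      c(C = cc$C, L = pl$L)
    })
  })
  cvals <- vapply(ens, `[[`, numeric(1), "C")
  lvals <- vapply(ens, `[[`, numeric(1), "L")
  c_rand <- mean(cvals)
  l_rand <- mean(lvals)
  if (c_rand <= 0 || l_rand <= 0)
    stop_rsn("null ensemble has zero clustering or path length")
  gamma <- metrics$C / c_rand
  lambda <- metrics$L / l_rand
  structure(
    list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
         ensemble = list(m = m, c_rand = c_rand, l_rand = l_rand,
                         C = cvals, L = lvals),
         network = g$network, subject_id = g$subject_id,
         threshold = g$threshold),
    class = "rsn_smallworld"
  )
}

#' @export
print.rsn_smallworld <- function(x, ...) {
  cat(sprintf("<rsn_smallworld> gamma=%.3f lambda=%.3f sigma=%.3f (m=%d)\n",
              x$gamma, x$lambda, x$sigma, x$ensemble$m))
  invisible(x)
}

#' Glance at small-world indices
#' @param x An `rsn_smallworld`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.rsn_smallworld <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id %||% NA_character_,
                 network = x$network %||% NA_character_,
                 threshold = x$threshold %||% NA_real_,
                 gamma = x$gamma, lambda = x$lambda, sigma = x$sigma,
                 c_rand = x$ensemble$c_rand, l_rand = x$ensemble$l_rand,
                 m = x$ensemble$m)
}

#' Theoretical random-graph baselines
#'
#' The classical Watts-Strogatz-era expectations for an Erdos-Renyi random
#' graph: `C_rand = k / n` and `L_rand = ln(n) / ln(k)`. Exposed as a
#' sanity cross-check only; the small-world indices always use the
#' empirical rewired ensemble, whose degree sequence matches the data.
#'
#' @param n Node count.
#' @param k_mean Mean degree (must satisfy `1 < k_mean < n`).
#' @return Named list `c_rand_theory`, `l_rand_theory`.
#' @export
theoretical_random <- function(n, k_mean) {
  assert_that(k_mean > 1, "k_mean must exceed 1")
  assert_that(n > k_mean, "n must exceed k_mean")
  list(c_rand_theory = k_mean / n,
       l_rand_theory = log(n) / log(k_mean))
}
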