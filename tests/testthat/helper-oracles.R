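# Independent brute-force oracles and tiny fixture builders.
# These deliberately avoid the package's graph code paths.

# adjacency matrix from an rsn_graph
adj_matrix <- function(g) {
  a <- matrix(FALSE, g$n_nodes, g$n_nodes)
  a[g$edges] <- TRUE
  a[g$edges[, c(2, 1), drop = FALSE]] <- TRUE
  a
}

# per-node clustering by explicit neighbor-pair enumeration
oracle_clustering <- function(a) {
  n <- nrow(a)
  sapply(seq_len(n), function(v) {
    nb <- which(a[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (i in seq_len(k - 1))
      for (j in (i + 1):k)
        if (a[nb[i], nb[j]]) links <- links + 1
    2 * links / (k * (k - 1))
  })
}

# all-pairs BFS distances in plain R
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  for (src in seq_len(n)) {
    dist <- rep(-1L, n)
    dist[src] <- 0L
    frontier <- src
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(a[v, ])) {
          if (dist[u] < 0) { dist[u] <- dist[v] + 1L; nxt <- c(nxt, u) }
        }
      }
      frontier <- nxt
    }
    d[src, ] <- ifelse(dist < 0, Inf, dist)
  }
  d
}

# mean shortest path over connected pairs of the largest component,
# via the BFS distance oracle
oracle_path_length <- function(a) {
  d <- oracle_distances(a)
  comp_sizes <- colSums(is.finite(d))
  members <- which(comp_sizes == max(comp_sizes))
  # largest component = the mutual-reachability class of its members
  members <- which(is.finite(d[members[1], ]))
  dd <- d[members, members]
  mean(dd[upper.tri(dd)])
}

# Erdos-Renyi G(n, p) as an rsn_graph
er_graph <- function(n, p) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  structure(list(n_nodes = n,
                 edges = matrix(as.integer(pairs[keep, , drop = FALSE]),
                                ncol = 2,
                                dimnames = list(NULL, c("i", "j"))),
                 threshold = NA_real_),
            class = "rsn_graph")
}

# Watts-Strogatz ring: n nodes, k neighbors each side = k/2, rewiring prob p
ws_graph <- function(n, k, p) {
  half <- k %/% 2
  a <- matrix(FALSE, n, n)
  for (v in seq_len(n))
    for (s in seq_len(half)) {
      u <- ((v - 1 + s) %% n) + 1
      a[v, u] <- a[u, v] <- TRUE
    }
  # rewire each lattice edge with probability p
  idx <- which(upper.tri(a) & a, arr.ind = TRUE)
  for (e in seq_len(nrow(idx))) {
    if (runif(1) < p) {
      v <- idx[e, 1]
      candidates <- which(!a[v, ] & seq_len(n) != v)
      if (length(candidates) > 0) {
        u_new <- candidates[sample.int(length(candidates), 1)]
        a[idx[e, 1], idx[e, 2]] <- a[idx[e, 2], idx[e, 1]] <- FALSE
        a[v, u_new] <- a[u_new, v] <- TRUE
      }
    }
  }
  idx <- which(upper.tri(a) & a, arr.ind = TRUE)
  structure(list(n_nodes = n,
                 edges = matrix(as.integer(idx), ncol = 2,
                                dimnames = list(NULL, c("i", "j"))),
                 threshold = NA_real_),
            class = "rsn_graph")
}

# a small, fast cohort configuration for unit tests
tiny_config <- function(n_subjects = 2, seed = 42, ...) {
  nets <- dplyr::bind_rows(
    network_spec("cogA", "cognitive", 60L, 4L, 0.85, 0.15, 0.75),
    network_spec("cogB", "cognitive", 60L, 4L, 0.85, 0.15, 0.75),
    network_spec("perA", "perceptual", 50L, 2L, 0.85, 0.20, 0.58),
    network_spec("perB", "perceptual", 50L, 2L, 0.85, 0.20, 0.58)
  )
  generator_config(n_subjects = n_subjects, networks = nets,
                   grid_dim = c(16L, 16L, 10L), seed = seed, ...)
}

# synthetic rsn_ts wrapper around a plain matrix
make_ts <- function(data, tr = 2, network = "NET", subject = "sub-01") {
  structure(
    list(network = network, subject_id = subject,
         voxel_ids = seq_len(nrow(data)), data = data, tr = tr,
         cleaned = c(regressed = TRUE, filtered = FALSE)),
    class = "rsn_ts"
  )
}
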