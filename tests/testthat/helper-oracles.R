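# Shared fixtures and independent oracles for the test suite.

feat <- default_featurizer()

# Build a molecule_graph from an edge matrix, all-carbon features.
mk_graph <- function(n, edges) {
  g <- molecule_graph(n, edges, symbols = rep("C", n))
  g$X <- feat$encode(g$symbols, degree_counts(g), integer(n))
  g
}

chain_graph <- function(n) mk_graph(n, if (n > 1) cbind(1:(n - 1), 2:n) else NULL)

# Random connected graph via G(n, p) rejection sampling (igraph).
random_connected_graph <- function(n, p = 0.3) {
  repeat {
    ig <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(ig)) break
  }
  mk_graph(n, igraph::as_edgelist(ig))
}

# Independent geodesic oracle: all simple paths of length <= K from every
# node (igraph DFS), kept iff the path length equals the endpoint distance.
oracle_geodesics <- function(graph, K) {
  ig <- to_igraph(graph)
  D <- igraph::distances(ig)
  out <- lapply(seq_len(K), function(k) list())
  for (s in seq_len(graph$n)) {
    sp <- igraph::all_simple_paths(ig, from = s, cutoff = K)
    for (p in sp) {
      v <- as.integer(p)
      k <- length(v) - 1L
      if (k >= 1L && k <= K && D[s, v[length(v)]] == k) {
        out[[k]][[length(out[[k]]) + 1L]] <- v
      }
    }
  }
  lapply(seq_len(K), function(k) {
    if (!length(out[[k]])) return(matrix(integer(0), ncol = k + 1L))
    do.call(rbind, out[[k]])
  })
}

# Order-free multiset fingerprint of a path matrix.
path_key <- function(m) sort(apply(m, 1L, paste, collapse = "-"))

expect_same_paths <- function(a, b) {
  expect_identical(path_key(a), path_key(b))
}

# Triangle-count oracle: T(v) = (A^3)_{vv} / 2.
oracle_clustering <- function(graph) {
  n <- graph$n
  A <- matrix(0, n, n)
  if (nrow(graph$edges)) {
    A[graph$edges] <- 1
    A[graph$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  tri <- diag(A %*% A %*% A) / 2
  deg <- rowSums(A)
  ifelse(deg < 2, 0, 2 * tri / (deg * (deg - 1)))
}

# Brute-force AUC by concordant-pair counting (ties = 0.5).
oracle_auc <- function(scores, y) {
  pos <- which(y == 1); neg <- which(y == 0)
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Small labelled regression dataset of chains for fitting smoke tests.
tiny_regression_data <- function(n_graphs = 8, seed = 3) {
  generate_chain_molecules(n_graphs, c(5, 9), target = "distance_pair_count",
                           k_star = 3, seed = seed)
}
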