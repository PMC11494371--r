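#' Single-source shortest-path distances (unweighted BFS)
#'
#' @param graph a [molecule_graph()].
#' @param source node index.
#' @return Numeric vector of hop distances; `Inf` for unreachable nodes.
#' @export
bfs_distances <- function(graph, source) {
  if (source < 1L || source > graph$n) stop("invalid source node")
  adj <- adjacency_list(graph)
  dist <- rep(Inf, graph$n)
  dist[source] <- 0
  queue <- source
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

#' Enumerate exact-length shortest paths (geodesics) from every node
#'
#' For each start node and each length k = 1..K, lists every simple path
#' whose length equals the graph distance between its endpoints — the path
#' sets delta(k) that path convolution aggregates. All geodesics between an
#' endpoint pair are kept, not one representative. Enumeration is a
#' depth-limited DFS from each node; a branch is extended to neighbour w at
#' depth t only if the BFS distance from the start to w equals t (every
#' prefix of a geodesic is a geodesic, so this pruning is exact). Neighbours
#' are visited in ascending index, making the output order deterministic.
#' With `geodesic_only = FALSE` all simple paths of length <= K are returned
#' instead (ablation variant).
#'
#' @param graph a [molecule_graph()].
#' @param K maximum path length (>= 1).
#' @param geodesic_only keep only shortest paths (default) or all simple paths.
#' @return A `path_set`: list with `K`, `paths` (list over k of integer
#'   matrices, one row per path, k+1 columns; column 1 is the start node) and
#'   `counts` (paths per k).
#' @examples
#' p4 <- molecule_graph(4, cbind(1:3, 2:4))
#' ps <- enumerate_paths(p4, 3)
#' ps$counts            # 6, 4, 2
#' ps$paths[[3]]        # 1 2 3 4 / 4 3 2 1
#' @export
enumerate_paths <- function(graph, K, geodesic_only = TRUE) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  adj <- adjacency_list(graph)
  buckets <- lapply(seq_len(K), function(k) list())
  for (s in seq_len(graph$n)) {
    dist_s <- if (geodesic_only) bfs_distances(graph, s) else NULL
    path <- integer(K + 1L)
    path[1L] <- s
    on_path <- logical(graph$n)
    on_path[s] <- TRUE
    dfs <- function(depth) {
      v <- path[depth + 1L]
      if (depth >= K) return()
      for (w in adj[[v]]) {
        if (on_path[w]) next
        if (geodesic_only && dist_s[w] != depth + 1) next
        path[depth + 2L] <<- w
        on_path[w] <<- TRUE
        buckets[[depth + 1L]][[length(buckets[[depth + 1L]]) + 1L]] <<-
          path[seq_len(depth + 2L)]
        dfs(depth + 1L)
        on_path[w] <<- FALSE
      }
    }
    dfs(0L)
  }
  paths <- lapply(seq_len(K), function(k) {
    b <- buckets[[k]]
    if (!length(b)) return(matrix(integer(0), ncol = k + 1L))
    do.call(rbind, b)
  })
  structure(
    list(K = K, paths = paths, counts = vapply(paths, nrow, integer(1))),
    class = "path_set"
  )
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("<path_set> K = %d; paths per length: %s\n",
              x$K, paste(x$counts, collapse = ", ")))
  invisible(x)
}

# Paths of length k starting at node s (rows of the bucket-k matrix).
paths_from <- function(pathset, k, s) {
  m <- pathset$paths[[k]]
  m[m[, 1L] == s, , drop = FALSE]
}

#' Check the geodesic-count complexity bound
#'
#' DFS enumeration from all nodes stores at most n * b^K paths, with b the
#' maximum degree. Returns `TRUE` iff the enumerated total respects that
#' bound.
#'
#' @param graph a [molecule_graph()].
#' @param K maximum path length used.
#' @param pathset optional precomputed [enumerate_paths()] result.
#' @return Logical scalar; attributes `total` and `bound` carry the numbers.
#' @export
path_count_bound_check <- function(graph, K, pathset = NULL) {
  if (is.null(pathset)) pathset <- enumerate_paths(graph, K)
  b <- if (nrow(graph$edges)) max(degree_counts(graph)) else 0L
  total <- sum(pathset$counts)
  bound <- graph$n * b^pathset$K
  structure(total <= bound, total = total, bound = bound)
}
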