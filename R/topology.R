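#' Local clustering coefficient
#'
#' For node v with degree deg(v) >= 2, the fraction of pairs of v's
#' neighbours that are themselves connected: 2 T(v) / (deg(v) (deg(v) - 1)),
#' with T(v) the number of edges among the neighbours. Defined as 0 for
#' degree < 2. Molecular graphs are triangle-poor, so these values sit near
#' zero for most atoms — the chain-dominated regime this package targets.
#'
#' @param graph a [molecule_graph()].
#' @param node optional node index; if `NULL`, coefficients for all nodes.
#' @return Numeric in \[0, 1\] (or a vector over all nodes).
#' @examples
#' tri <- molecule_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
#' clustering_coefficient(tri, 1)   # 1
#' @export
clustering_coefficient <- function(graph, node = NULL) {
  adj <- adjacency_list(graph)
  cc_one <- function(v) {
    nb <- adj[[v]]
    d <- length(nb)
    if (d < 2L) return(0)
    t_v <- 0L
    for (i in seq_len(d - 1L)) {
      t_v <- t_v + sum(adj[[nb[i]]] %in% nb[(i + 1L):d])
    }
    2 * t_v / (d * (d - 1L))
  }
  if (!is.null(node)) {
    if (node < 1L || node > graph$n) stop("invalid node index")
    return(cc_one(node))
  }
  vapply(seq_len(graph$n), cc_one, numeric(1))
}

#' Topology diagnostics over a set of molecular graphs
#'
#' Pools per-node clustering coefficients across all graphs (the average is
#' over nodes, not a mean of per-graph means) and tabulates degrees. The
#' maximum degree is the branching bound `b` that controls the cost of
#' geodesic enumeration (at most n * b^K paths).
#'
#' @param graphs list of [molecule_graph()], or a [molpath_dataset()].
#' @return A `topology_report`: `per_node_cc`, `avg_cc`, `max_degree`,
#'   `degree_histogram` (named counts), `n_nodes`, `n_graphs`.
#' @export
dataset_topology <- function(graphs) {
  if (inherits(graphs, "molpath_dataset")) graphs <- graphs$graphs
  if (!length(graphs)) stop("empty graph list")
  cc <- unlist(lapply(graphs, clustering_coefficient))
  deg <- unlist(lapply(graphs, degree_counts))
  hist <- table(factor(deg, levels = 0:max(deg)))
  structure(
    list(per_node_cc = cc,
         avg_cc = mean(cc),
         max_degree = as.integer(max(deg)),
         degree_histogram = as.integer(hist),
         degree_levels = as.integer(names(hist)),
         n_nodes = length(cc),
         n_graphs = length(graphs)),
    class = "topology_report"
  )
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("<topology_report> %d graphs, %d nodes\n", x$n_graphs, x$n_nodes))
  cat(sprintf("  average clustering coefficient: %.4f\n", x$avg_cc))
  cat(sprintf("  max degree b: %d\n", x$max_degree))
  invisible(x)
}
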