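#' Construct an attributed molecular graph
#'
#' A `molecule_graph` is an undirected simple graph: nodes are (heavy) atoms,
#' edges are bonds. Node attributes live in the feature matrix `X` (one row
#' per node); `symbols` optionally carries atom symbols for debugging.
#'
#' @param n integer node count (>= 1 unless `allow_empty`).
#' @param edges two-column integer matrix of undirected edges, 1-based node
#'   indices; may have zero rows. Self-loops and duplicate edges are rejected.
#' @param X optional numeric matrix with `n` rows of initial node features.
#' @param symbols optional character vector of length `n` (atom symbols).
#' @return An object of class `molecule_graph` with fields `n`, `edges`
#'   (canonicalised so that `edges[,1] < edges[,2]`, sorted), `X`, `symbols`.
#' @examples
#' g <- molecule_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))  # cyclopropane skeleton
#' degree_counts(g)
#' @export
molecule_graph <- function(n, edges, X = NULL, symbols = NULL) {
  n <- as.integer(n)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (n < 0L) stop("node count must be >= 0")
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n)) {
      stop("edge endpoints must lie in [1, n]")
    }
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    edges <- t(apply(edges, 1L, sort))
    edges <- matrix(as.integer(edges), ncol = 2L)
    key <- edges[, 1L] * (n + 1L) + edges[, 2L]
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
    edges <- edges[order(key), , drop = FALSE]
  }
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("X must have exactly n rows")
    storage.mode(X) <- "double"
  }
  if (!is.null(symbols) && length(symbols) != n) {
    stop("symbols must have length n")
  }
  structure(
    list(n = n, edges = edges, X = X, symbols = symbols),
    class = "molecule_graph"
  )
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf(
    "<molecule_graph> %d nodes, %d edges%s\n", x$n, nrow(x$edges),
    if (!is.null(x$X)) sprintf(", %d features/node", ncol(x$X)) else ""
  ))
  if (!is.null(x$symbols)) {
    cat(" atoms:", paste(x$symbols, collapse = " "), "\n")
  }
  invisible(x)
}

# Adjacency list: integer vector of neighbours (ascending) per node.
adjacency_list <- function(graph) {
  adj <- vector("list", graph$n)
  for (v in seq_len(graph$n)) adj[[v]] <- integer(0)
  e <- graph$edges
  if (nrow(e) > 0L) {
    nb <- split(c(e[, 2L], e[, 1L]), c(e[, 1L], e[, 2L]))
    for (nm in names(nb)) adj[[as.integer(nm)]] <- sort(as.integer(nb[[nm]]))
  }
  adj
}

#' Node degrees of a molecular graph
#'
#' @param graph a `molecule_graph`.
#' @return Integer vector of length `n`.
#' @export
degree_counts <- function(graph) {
  deg <- integer(graph$n)
  if (nrow(graph$edges) > 0L) {
    tab <- tabulate(c(graph$edges[, 1L], graph$edges[, 2L]), nbins = graph$n)
    deg <- as.integer(tab)
  }
  deg
}

# igraph conversion (keeps isolated vertices); used for isomorphism checks
# and canonical hashing in the scaffold split.
to_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = graph$n, directed = FALSE)
  if (nrow(graph$edges) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(graph$edges)))
  }
  g
}

# Relabel nodes by a permutation: node v becomes perm[v].
permute_graph <- function(graph, perm) {
  inv <- integer(graph$n)
  inv[perm] <- seq_len(graph$n)
  e <- graph$edges
  if (nrow(e) > 0L) e <- cbind(perm[e[, 1L]], perm[e[, 2L]])
  X <- graph$X
  if (!is.null(X)) X <- X[inv, , drop = FALSE]
  sym <- graph$symbols
  if (!is.null(sym)) sym <- sym[inv]
  molecule_graph(graph$n, e, X = X, symbols = sym)
}
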