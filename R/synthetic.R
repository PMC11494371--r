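# Synthetic fixtures and generators. Everything here is synthetic data built
# in code: hand-verifiable small graphs with golden geodesic sets, and random
# low-clustering chain molecules whose targets depend on nodes several hops
# apart — the regime (clustering near zero, dominating chains) that motivates
# path convolution, and a falsifiable long-range learning benchmark.

#' Hand-verified fixture graphs with golden geodesic sets
#'
#' Five small graphs with their complete exact-length shortest-path sets up
#' to K = 3, enumerated by hand: the 4-node path P4, the triangle C3 (whose
#' delta(2) is empty — every 2-step simple walk ends at a distance-1 node),
#' the 6-cycle C6 (two geodesics of length 3 from every node), the 5-leaf
#' star S5, and the 4-cycle with chord {1,3}.
#'
#' @return Named list; each entry has `graph` (a [molecule_graph()]) and
#'   `golden` (list over k = 1..3 of path matrices, one row per path).
#' @export
make_fixture_graphs <- function() {
  feat <- default_featurizer()
  mk <- function(n, edges) {
    g <- molecule_graph(n, edges, symbols = rep("C", n))
    g$X <- feat$encode(g$symbols, degree_counts(g), integer(n))
    g
  }
  pm <- function(..., k) {
    v <- c(...)
    if (!length(v)) return(matrix(integer(0), ncol = k + 1L))
    matrix(as.integer(v), ncol = k + 1L, byrow = TRUE)
  }
  list(
    P4 = list(
      graph = mk(4, cbind(1:3, 2:4)),
      golden = list(
        pm(1,2, 2,1, 2,3, 3,2, 3,4, 4,3, k = 1),
        pm(1,2,3, 3,2,1, 2,3,4, 4,3,2, k = 2),
        pm(1,2,3,4, 4,3,2,1, k = 3))),
    C3 = list(
      graph = mk(3, rbind(c(1,2), c(2,3), c(1,3))),
      golden = list(
        pm(1,2, 2,1, 2,3, 3,2, 1,3, 3,1, k = 1),
        pm(k = 2),
        pm(k = 3))),
    C6 = list(
      graph = mk(6, rbind(cbind(1:5, 2:6), c(6, 1))),
      golden = list(
        pm(1,2, 2,1, 2,3, 3,2, 3,4, 4,3, 4,5, 5,4, 5,6, 6,5, 6,1, 1,6, k = 1),
        pm(1,2,3, 3,2,1, 2,3,4, 4,3,2, 3,4,5, 5,4,3, 4,5,6, 6,5,4,
           5,6,1, 1,6,5, 6,1,2, 2,1,6, k = 2),
        pm(1,2,3,4, 4,3,2,1, 2,3,4,5, 5,4,3,2, 3,4,5,6, 6,5,4,3,
           4,5,6,1, 1,6,5,4, 5,6,1,2, 2,1,6,5, 6,1,2,3, 3,2,1,6, k = 3))),
    S5 = list(
      graph = mk(6, cbind(1L, 2:6)),
      golden = list(
        pm(1,2, 1,3, 1,4, 1,5, 1,6, 2,1, 3,1, 4,1, 5,1, 6,1, k = 1),
        pm(as.vector(t(do.call(rbind, lapply(2:6, function(i) {
          js <- setdiff(2:6, i)
          cbind(i, 1L, js)
        })))), k = 2),
        pm(k = 3))),
    C4_chord = list(
      graph = mk(4, rbind(c(1,2), c(2,3), c(3,4), c(4,1), c(1,3))),
      golden = list(
        pm(1,2, 2,1, 2,3, 3,2, 3,4, 4,3, 4,1, 1,4, 1,3, 3,1, k = 1),
        pm(2,1,4, 2,3,4, 4,1,2, 4,3,2, k = 2),
        pm(k = 3)))
  )
}

#' Generate random low-clustering chain molecules with long-range targets
#'
#' Random trees built by chain extension with occasional short branches
#' (heavy-atom degree capped at 4, all-carbon skeletons, so every graph is a
#' valence-plausible alkane). Trees contain no triangles, hence the batch
#' clustering coefficient is exactly 0 — the chain-dominated regime. The
#' graph-level target is an exact structural count, so ground truth is known
#' and depends on node pairs `k_star` hops apart by construction:
#' `"distance_pair_count"` counts unordered node pairs at graph distance
#' exactly `k_star`; `"geodesic_count"` counts geodesics of length `k_star`
#' (ordered; twice the pair count on trees); `"substituent_parity"` is the
#' 0/1 parity of the number of branch points (degree >= 3).
#'
#' @param n_graphs number of molecules.
#' @param nodes_range integer range of molecule sizes, sampled uniformly.
#' @param target one of `"distance_pair_count"`, `"geodesic_count"`,
#'   `"substituent_parity"`.
#' @param k_star hop distance the target depends on.
#' @param noise_sd standard deviation of Gaussian noise added to regression
#'   targets (0 = exact counts).
#' @param relative_noise if `TRUE`, `noise_sd` is a fraction of the clean
#'   targets' standard deviation over the batch.
#' @param as_classification threshold the count at the batch median to get a
#'   0/1 label (count targets only).
#' @param branch_prob probability that a new atom starts a branch instead of
#'   extending the current chain.
#' @param seed RNG seed; the same seed reproduces the batch exactly.
#' @return A [molpath_dataset()] with one task. `attr(, "clean_y")` holds
#'   the noise-free targets.
#' @export
generate_chain_molecules <- function(n_graphs = 256L, nodes_range = c(8L, 18L),
                                     target = c("distance_pair_count",
                                                "geodesic_count",
                                                "substituent_parity"),
                                     k_star = 4L, noise_sd = 0,
                                     relative_noise = FALSE,
                                     as_classification = FALSE,
                                     branch_prob = 0.25, seed = 1L) {
  target <- match.arg(target)
  nodes_range <- as.integer(range(nodes_range))
  if (nodes_range[2L] < k_star + 1L) {
    stop(sprintf("nodes_range max %d cannot realise a %d-hop target",
                 nodes_range[2L], k_star))
  }
  feat <- default_featurizer()
  with_seed(seed, {
    graphs <- vector("list", n_graphs)
    clean <- numeric(n_graphs)
    for (i in seq_len(n_graphs)) {
      n <- nodes_range[1L] + sample.int(nodes_range[2L] - nodes_range[1L] + 1L, 1L) - 1L
      parent <- integer(n)
      deg <- integer(n)
      tip <- 1L  # current chain end
      for (v in 2:n) {
        branch <- stats::runif(1) < branch_prob
        cand <- if (!branch && deg[tip] < 4L) {
          tip
        } else {
          elig <- which(deg[seq_len(v - 1L)] < 4L)
          elig[sample.int(length(elig), 1L)]
        }
        parent[v] <- cand
        deg[cand] <- deg[cand] + 1L
        deg[v] <- deg[v] + 1L
        tip <- v
      }
      g <- molecule_graph(n, cbind(2:n, parent[2:n]),
                          symbols = rep("C", n))
      g$X <- feat$encode(g$symbols, degree_counts(g), integer(n))
      graphs[[i]] <- g
      clean[i] <- switch(
        target,
        distance_pair_count = {
          dm <- vapply(seq_len(n), function(s) bfs_distances(g, s), numeric(n))
          sum(dm == k_star) / 2
        },
        geodesic_count = {
          dm <- vapply(seq_len(n), function(s) bfs_distances(g, s), numeric(n))
          sum(dm == k_star)
        },
        substituent_parity = sum(degree_counts(g) >= 3L) %% 2
      )
    }
    y <- clean
    task_type <- "regression"
    if (target == "substituent_parity" || as_classification) {
      task_type <- "classification"
      if (target != "substituent_parity") {
        y <- as.numeric(clean > stats::median(clean))
      }
    } else if (noise_sd > 0) {
      sdv <- if (relative_noise) noise_sd * stats::sd(clean) else noise_sd
      y <- clean + stats::rnorm(n_graphs, sd = sdv)
    }
    ds <- molpath_dataset(graphs, matrix(y, ncol = 1L), task_type,
                          task_names = target)
    attr(ds, "clean_y") <- clean
    ds
  })
}

#' Write a molecular graph as a SMILES string
#'
#' Depth-first spanning-tree traversal with ring-closure digits for cycle
#' bonds; element symbols are taken from the graph (default carbon). Round
#' trips through [smiles_to_graph()] up to graph isomorphism.
#'
#' @param graph a [molecule_graph()]; must be connected.
#' @return A SMILES string (e.g. `"CCCC"` for butane, `"C1CCCCC1"` for
#'   cyclohexane).
#' @export
graph_to_smiles <- function(graph) {
  n <- graph$n
  if (n == 0L) stop("empty graph")
  sym <- if (is.null(graph$symbols)) rep("C", n) else graph$symbols
  adj <- adjacency_list(graph)
  visited <- logical(n)
  parent <- rep(NA_integer_, n)
  # DFS tree; non-tree edges become ring closures
  visited[1L] <- TRUE
  children <- vector("list", n)
  ring_bonds <- list()
  seen_edge <- matrix(FALSE, n, n)
  dfs <- function(v) {
    for (w in adj[[v]]) {
      if (!visited[w]) {
        visited[w] <<- TRUE
        parent[w] <<- v
        children[[v]] <<- c(children[[v]], w)
        seen_edge[v, w] <<- seen_edge[w, v] <<- TRUE
        dfs(w)
      } else if (!seen_edge[v, w] && w != parent[v]) {
        seen_edge[v, w] <<- seen_edge[w, v] <<- TRUE
        ring_bonds[[length(ring_bonds) + 1L]] <<- c(v, w)
      }
    }
  }
  dfs(1L)
  if (!all(visited)) stop("graph is disconnected; cannot serialise")
  ring_at <- vector("list", n)
  for (r in seq_along(ring_bonds)) {
    for (v in ring_bonds[[r]]) ring_at[[v]] <- c(ring_at[[v]], r)
  }
  digit <- function(r) if (r <= 9L) as.character(r) else sprintf("%%%02d", r)
  write_atom <- function(v) {
    s <- sym[v]
    atom <- if (nchar(s) == 1L && s %in% c("B","C","N","O","F","P","S","I")) s
            else if (s %in% c("Cl", "Br")) s
            else paste0("[", s, "]")
    out <- paste0(atom, paste(vapply(ring_at[[v]], digit, character(1)),
                              collapse = ""))
    kids <- children[[v]]
    if (length(kids)) {
      subs <- vapply(kids, write_atom, character(1))
      if (length(subs) > 1L) {
        out <- paste0(out, paste0("(", subs[-length(subs)], ")",
                                  collapse = ""), subs[length(subs)])
      } else {
        out <- paste0(out, subs)
      }
    }
    out
  }
  write_atom(1L)
}

#' Write a synthetic dataset as a MoleculeNet-style CSV
#'
#' Serialises each graph to SMILES and writes a `smiles` column plus the task
#' columns, so the full CSV ingestion path can be exercised end-to-end on
#' generated data. Graphs that fail to serialise are skipped with a warning.
#'
#' @param dataset a [molpath_dataset()] of serialisable graphs.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
emit_smiles_csv <- function(dataset, path) {
  smi <- vapply(seq_along(dataset$graphs), function(i) {
    tryCatch(graph_to_smiles(dataset$graphs[[i]]), error = function(e) {
      warning("skipping unserialisable graph ", i, ": ", conditionMessage(e))
      NA_character_
    })
  }, character(1))
  keep <- !is.na(smi)
  df <- data.frame(smiles = smi[keep],
                   dataset$y[keep, , drop = FALSE], check.names = FALSE)
  names(df) <- c("smiles", dataset$task_names)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
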