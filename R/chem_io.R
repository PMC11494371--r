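#' Parse a SMILES string into an attributed molecular graph
#'
#' Heavy atoms become nodes, bonds become undirected edges; hydrogens are
#' implicit and dropped if written explicitly. Node features are produced by
#' the featurizer (symbol / degree / formal-charge one-hots by default).
#'
#' @param smiles a single SMILES string.
#' @param featurizer a featurizer from [default_featurizer()].
#' @return A [molecule_graph()].
#' @examples
#' g <- smiles_to_graph("CCCC")   # butane: a 4-node path graph
#' g$n          # 4
#' g$edges      # 1-2, 2-3, 3-4
#' @export
smiles_to_graph <- function(smiles, featurizer = default_featurizer()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) {
      stop(sprintf("unparseable SMILES '%s': %s", smiles, conditionMessage(e)),
           call. = FALSE)
    }
  )
  # Parse the V2000 molfile text: counts line, atom block (x y z symbol
  # massdiff chargecode ...), bond block (a1 a2 order), M CHG overrides.
  lines <- as.character(ChemmineR::sdf2str(sdf[[1]]))
  counts <- strsplit(trimws(lines[4L]), "\\s+")[[1L]]
  n_atoms <- as.integer(counts[1L])
  n_bonds <- as.integer(counts[2L])
  if (is.na(n_atoms) || n_atoms < 1L) {
    stop(sprintf("SMILES '%s' yields zero atoms", smiles), call. = FALSE)
  }
  atom_tok <- lapply(lines[4L + seq_len(n_atoms)],
                     function(l) strsplit(trimws(l), "\\s+")[[1L]])
  symbols <- vapply(atom_tok, `[`, character(1), 4L)
  # charge codes: 0 none, 1..3 -> +3..+1, 4 radical, 5..7 -> -1..-3
  code <- vapply(atom_tok, function(t) {
    suppressWarnings(as.integer(t[6L]))
  }, integer(1))
  code[is.na(code)] <- 0L
  charges <- integer(n_atoms)
  charges[code %in% c(1:3, 5:7)] <- 4L - code[code %in% c(1:3, 5:7)]
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    tok <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)), "\\s+")[[1L]])
    np <- tok[1L]
    for (p in seq_len(np)) charges[tok[2L * p]] <- tok[2L * p + 1L]
  }
  edges <- if (n_bonds > 0L) {
    bt <- lapply(lines[4L + n_atoms + seq_len(n_bonds)],
                 function(l) strsplit(trimws(l), "\\s+")[[1L]])
    cbind(vapply(bt, function(t) as.integer(t[1L]), integer(1)),
          vapply(bt, function(t) as.integer(t[2L]), integer(1)))
  } else {
    matrix(integer(0), ncol = 2L)
  }
  keep <- which(symbols != "H")
  if (length(keep) == 0L) {
    stop(sprintf("SMILES '%s' has no heavy atoms", smiles), call. = FALSE)
  }
  remap <- integer(n_atoms)
  remap[keep] <- seq_along(keep)
  if (nrow(edges) > 0L) {
    ok <- symbols[edges[, 1L]] != "H" & symbols[edges[, 2L]] != "H"
    edges <- edges[ok, , drop = FALSE]
    edges <- cbind(remap[edges[, 1L]], remap[edges[, 2L]])
  }
  symbols <- symbols[keep]
  charges <- charges[keep]
  g <- molecule_graph(length(keep), edges, symbols = symbols)
  g$X <- featurizer$encode(symbols, degree_counts(g), charges)
  g
}

#' Bundle molecular graphs with (possibly missing) task labels
#'
#' @param graphs list of [molecule_graph()] objects (each with a feature
#'   matrix of identical width).
#' @param y numeric matrix, graphs x tasks; `NA` marks a missing label.
#' @param task_type `"regression"` or `"classification"`.
#' @param task_names optional character vector of task names.
#' @param smiles optional character vector of source SMILES.
#' @return A `molpath_dataset`: list with `graphs`, `y`, `mask`, `task_type`,
#'   `task_names`, `smiles`. Masked-out entries never reach loss or metrics.
#' @export
molpath_dataset <- function(graphs, y, task_type = c("regression", "classification"),
                            task_names = NULL, smiles = NULL) {
  task_type <- match.arg(task_type)
  y <- as.matrix(y)
  if (length(graphs) != nrow(y)) stop("length(graphs) must equal nrow(y)")
  mask <- !is.na(y)
  if (task_type == "classification") {
    obs <- y[mask]
    if (length(obs) && !all(obs %in% c(0, 1))) {
      stop("classification labels must be 0/1")
    }
  }
  d0 <- unique(vapply(graphs, function(g) ncol(g$X), integer(1)))
  if (length(d0) > 1L) stop("all graphs must share the same feature width")
  if (is.null(task_names)) task_names <- paste0("task", seq_len(ncol(y)))
  structure(
    list(graphs = graphs, y = y, mask = mask, task_type = task_type,
         task_names = task_names, smiles = smiles, d0 = d0),
    class = "molpath_dataset"
  )
}

#' @export
print.molpath_dataset <- function(x, ...) {
  cat(sprintf("<molpath_dataset> %d molecules, %d %s task(s), %.1f%% labels present\n",
              length(x$graphs), ncol(x$y), x$task_type, 100 * mean(x$mask)))
  invisible(x)
}

#' @export
`[.molpath_dataset` <- function(x, i) {
  molpath_dataset(x$graphs[i], x$y[i, , drop = FALSE], x$task_type,
                  x$task_names, if (!is.null(x$smiles)) x$smiles[i])
}

#' @export
length.molpath_dataset <- function(x) length(x$graphs)

#' Read a MoleculeNet-style CSV into a labelled dataset
#'
#' One SMILES column plus one or more numeric task columns. Rows whose SMILES
#' fails to parse (or whose label cells are non-empty but non-numeric, or not
#' 0/1 for classification) are dropped and counted; empty label cells become
#' masked-out entries.
#'
#' @param csv_path path to a UTF-8 CSV with a header row.
#' @param smiles_col name of the SMILES column.
#' @param task_cols character vector of task column names.
#' @param task_type `"regression"` or `"classification"`.
#' @param featurizer atom featurizer.
#' @return A [molpath_dataset()]; `attr(, "report")` holds `dropped` (count)
#'   and `dropped_smiles`.
#' @export
read_dataset <- function(csv_path, smiles_col = "smiles", task_cols,
                         task_type = c("regression", "classification"),
                         featurizer = default_featurizer()) {
  task_type <- match.arg(task_type)
  if (!file.exists(csv_path)) stop("file not found: ", csv_path)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c(smiles_col, task_cols), names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  graphs <- list(); keep <- logical(nrow(df)); dropped_smiles <- character(0)
  ymat <- matrix(NA_real_, nrow(df), length(task_cols),
                 dimnames = list(NULL, task_cols))
  for (i in seq_len(nrow(df))) {
    smi <- df[[smiles_col]][i]
    row_ok <- TRUE
    g <- tryCatch(smiles_to_graph(smi, featurizer), error = function(e) NULL)
    if (is.null(g)) row_ok <- FALSE
    if (row_ok) {
      for (j in seq_along(task_cols)) {
        cell <- df[[task_cols[j]]][i]
        if (is.na(cell) || (is.character(cell) && !nzchar(trimws(cell)))) next
        val <- suppressWarnings(as.numeric(cell))
        if (is.na(val) || (task_type == "classification" && !val %in% c(0, 1))) {
          row_ok <- FALSE
          break
        }
        ymat[i, j] <- val
      }
    }
    if (row_ok) {
      keep[i] <- TRUE
      graphs[[length(graphs) + 1L]] <- g
    } else {
      dropped_smiles <- c(dropped_smiles, as.character(smi))
    }
  }
  if (!any(keep)) stop("all rows dropped while reading ", csv_path)
  ds <- molpath_dataset(graphs, ymat[keep, , drop = FALSE], task_type,
                        task_names = task_cols,
                        smiles = as.character(df[[smiles_col]][keep]))
  attr(ds, "report") <- list(dropped = sum(!keep), dropped_smiles = dropped_smiles)
  ds
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Split a dataset into train / validation / test at 8:1:1
#'
#' Sizes are floor(0.8 N), floor(0.1 N) and the remainder. `"random"`
#' shuffles uniformly; `"scaffold"` groups molecules by their ring-system
#' framework (all acyclic side chains pruned, Bemis--Murcko style) and fills
#' the subsets group-by-group from the largest scaffold down, so test
#' chemotypes are unseen in training.
#'
#' @param dataset a [molpath_dataset()].
#' @param seed integer seed; the same seed reproduces the same index sets.
#' @param method `"random"` (default) or `"scaffold"`.
#' @return List with `train`, `valid`, `test` (datasets) and `indices`
#'   (list of the three 1-based index vectors) plus the `seed` used.
#' @export
split_dataset <- function(dataset, seed = 1L, method = c("random", "scaffold")) {
  method <- match.arg(method)
  N <- length(dataset$graphs)
  if (N < 1L) stop("dataset is empty")
  if (N < 10L) warning("fewer than 10 records; split sizes will be degenerate")
  n_train <- max(1L, as.integer(floor(0.8 * N)))
  n_valid <- as.integer(floor(0.1 * N))
  idx <- if (method == "random") {
    perm <- with_seed(seed, sample.int(N))
    list(train = sort(perm[seq_len(n_train)]),
         valid = sort(perm[n_train + seq_len(n_valid)]),
         test  = sort(perm[setdiff(seq_len(N), seq_len(n_train + n_valid))]))
  } else {
    keys <- vapply(dataset$graphs, scaffold_key, character(1))
    groups <- split(seq_len(N), keys)
    ord <- with_seed(seed, {
      sizes <- lengths(groups)
      order(-sizes, sample.int(length(groups)))  # big first, random ties
    })
    tr <- va <- te <- integer(0)
    for (g in groups[ord]) {
      if (length(tr) + length(g) <= n_train || length(tr) < n_train) {
        tr <- c(tr, g)
      } else if (length(va) < n_valid) {
        va <- c(va, g)
      } else {
        te <- c(te, g)
      }
    }
    list(train = sort(tr), valid = sort(va), test = sort(te))
  }
  list(train = dataset[idx$train], valid = dataset[idx$valid],
       test = dataset[idx$test], indices = idx, seed = seed, method = method)
}

# Ring-system framework key: prune degree-1 nodes to a fixed point, then hash
# the remaining element-labelled subgraph canonically (igraph/BLISS).
scaffold_key <- function(graph) {
  keep <- rep(TRUE, graph$n)
  repeat {
    e <- graph$edges
    e <- e[keep[e[, 1L]] & keep[e[, 2L]], , drop = FALSE]
    deg <- tabulate(c(e[, 1L], e[, 2L]), nbins = graph$n)
    leaf <- keep & deg <= 1L
    if (!any(leaf)) break
    keep[leaf] <- FALSE
  }
  if (!any(keep)) return("acyclic")
  old <- which(keep)
  remap <- integer(graph$n); remap[old] <- seq_along(old)
  e <- graph$edges
  e <- e[keep[e[, 1L]] & keep[e[, 2L]], , drop = FALSE]
  sub <- molecule_graph(length(old), cbind(remap[e[, 1L]], remap[e[, 2L]]))
  sym <- if (is.null(graph$symbols)) rep("C", length(old)) else graph$symbols[old]
  ig <- to_igraph(sub)
  colors <- as.integer(factor(sym))
  cp <- igraph::canonical_permutation(ig, colors = colors)$labeling
  pe <- sub$edges
  pe <- cbind(cp[pe[, 1L]], cp[pe[, 2L]])
  pe <- t(apply(pe, 1L, sort))
  ord <- order(pe[, 1L], pe[, 2L])
  paste(c(sym[order(cp)], as.vector(t(pe[ord, , drop = FALSE]))), collapse = ",")
}

#' Write split indices to a CSV file
#'
#' Three columns: `index` (1-based record index), `subset`
#' (train/valid/test), `seed`.
#'
#' @param split result of [split_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_csv <- function(split, path) {
  df <- do.call(rbind, lapply(c("train", "valid", "test"), function(s) {
    if (!length(split$indices[[s]])) return(NULL)
    data.frame(index = split$indices[[s]], subset = s, seed = split$seed)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
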