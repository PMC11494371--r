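test_that("SMILES parsing produces the expected heavy-atom graphs", {
  g <- smiles_to_graph("CC")
  expect_equal(g$n, 2L)
  expect_equal(g$edges, matrix(c(1L, 2L), 1))
  g <- smiles_to_graph("C1CC1")
  expect_equal(g$n, 3L)
  expect_same_paths(g$edges, rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  g <- smiles_to_graph("CCCC")
  expect_equal(g$n, 4L)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(sort(degree_counts(g)), c(1L, 1L, 2L, 2L))
  expect_error(smiles_to_graph("not(a(smiles"), "unparseable")
})

test_that("atom featurizer one-hots symbol, degree and charge", {
  g <- smiles_to_graph("CC(=O)[O-]")  # acetate: charge -1 on one oxygen
  expect_equal(ncol(g$X), 22L)
  expect_true(all(rowSums(g$X) == 3))  # exactly one hot per block
  # charge block spans columns 18..22 (codes -2..2); the anionic oxygen
  # activates the -1 slot, the rest the 0 slot
  chg_block <- g$X[, 18:22]
  expect_equal(sum(chg_block[, 2]), 1)
  expect_equal(sum(chg_block[, 3]), 3)
})

test_that("graphs are invariant to SMILES atom ordering (isomorphism)", {
  pairs <- list(c("CCO", "OCC"), c("CC(C)C", "CC(C)C"),
                c("c1ccccc1O", "Oc1ccccc1"), c("C1CCCCC1C", "CC1CCCCC1"))
  for (p in pairs) {
    g1 <- smiles_to_graph(p[1]); g2 <- smiles_to_graph(p[2])
    expect_equal(g1$n, g2$n)
    expect_true(igraph::isomorphic(to_igraph(g1), to_igraph(g2)))
  }
})

test_that("CSV reading drops bad rows and masks empty labels", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("smiles,act,tox",
               "CCO,1.2,0.5",
               "xx((bad,2.0,1.0",
               "CCC,,3.5",
               "C1CCCCC1,0.1,",
               "CCN,4.0,5.0"), csv)
  ds <- read_dataset(csv, "smiles", c("act", "tox"), "regression")
  expect_equal(length(ds$graphs), 4L)
  expect_equal(attr(ds, "report")$dropped, 1L)
  expect_equal(sum(!ds$mask), 2L)          # two empty cells masked out
  expect_error(read_dataset(csv, "smiles", c("nope"), "regression"), "missing column")

  # non-numeric regression cell is a record-level error (row dropped)
  writeLines(c("smiles,y", "CCO,1.0", "CCC,abc"), csv)
  ds2 <- read_dataset(csv, "smiles", "y", "regression")
  expect_equal(length(ds2$graphs), 1L)
  expect_equal(attr(ds2, "report")$dropped, 1L)

  # classification labels must be 0/1
  writeLines(c("smiles,y", "CCO,1", "CCC,2"), csv)
  ds3 <- read_dataset(csv, "smiles", "y", "classification")
  expect_equal(attr(ds3, "report")$dropped, 1L)
})

test_that("8:1:1 split has floor sizes, is a partition, and is deterministic", {
  make_ds <- function(N) {
    g <- chain_graph(3)
    molpath_dataset(rep(list(g), N), matrix(rnorm(N), ncol = 1))
  }
  ds <- make_ds(10)
  sp <- split_dataset(ds, seed = 0)
  expect_equal(lengths(sp$indices), c(train = 8L, valid = 1L, test = 1L))
  sp2 <- split_dataset(ds, seed = 0)
  expect_identical(sp$indices, sp2$indices)

  ds <- make_ds(642)  # FreeSolv-sized
  sp <- split_dataset(ds, seed = 7)
  expect_equal(lengths(sp$indices), c(train = 513L, valid = 64L, test = 65L))
  all_idx <- sort(unlist(sp$indices))
  expect_identical(unname(all_idx), 1:642)          # partition: union is everything
  expect_equal(anyDuplicated(unlist(sp$indices)), 0L)

  expect_warning(split_dataset(make_ds(5), seed = 1), "fewer than 10")
})

test_that("scaffold split keeps each ring framework in one subset", {
  smis <- c(rep("Cc1ccccc1", 8), rep("CC1CCCCC1", 6), rep("CCCCC", 4),
            rep("CC1CCC1", 2))
  graphs <- lapply(smis, smiles_to_graph)
  ds <- molpath_dataset(graphs, matrix(rnorm(20), ncol = 1))
  sp <- split_dataset(ds, seed = 1, method = "scaffold")
  keys <- vapply(graphs, molpath:::scaffold_key, character(1))
  subset_of <- rep(NA_character_, 20)
  for (s in c("train", "valid", "test")) subset_of[sp$indices[[s]]] <- s
  for (k in unique(keys)) {
    expect_equal(length(unique(subset_of[keys == k])), 1L)
  }
  expect_identical(sort(unname(unlist(sp$indices))), 1:20)
})

test_that("split indices round-trip through the CSV report", {
  ds <- molpath_dataset(rep(list(chain_graph(2)), 12),
                        matrix(rnorm(12), ncol = 1))
  sp <- split_dataset(ds, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_split_csv(sp, f)
  df <- read.csv(f)
  expect_equal(sort(df$index[df$subset == "train"]), sp$indices$train)
  expect_true(all(df$seed == 3))
})
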