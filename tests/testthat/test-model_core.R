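# Forward/backward machinery of the path-convolution stack.

test_that("IRDC input algebra matches the closed form", {
  set.seed(2)
  H0 <- matrix(rnorm(12), 4, 3)
  H1 <- matrix(rnorm(12), 4, 3)
  H2 <- matrix(rnorm(12), 4, 3)
  H <- list(H0, H1, H2)
  for (lam in c(0.1, 0.5, 1.0)) {
    expect_equal(irdc_input(H, 1, lam), (1 - lam) * H0, tolerance = 1e-15)
  }
  # hand arithmetic: one node, one feature, H(0)=[2], H(1)=[1], lambda=0.5
  expect_equal(irdc_input(list(matrix(2), matrix(1)), 2, 0.5),
               matrix(0.5), tolerance = 1e-12)
  # lambda = 1: pure negative sum of previous layers
  expect_equal(irdc_input(H, 3, 1), -(H1 + H2), tolerance = 1e-15)
  # ablation pathway returns the previous layer's output unchanged
  expect_identical(irdc_input(H, 3, 0.5, use_irdc = FALSE), H2)
})

test_that("initial embedding is the affine map of the feature matrix", {
  g <- chain_graph(3)
  ds <- molpath_dataset(list(g), matrix(1), "regression")
  cfg <- molpath_config(K = 1, d = 4)
  set.seed(4)
  par <- init_params(ds$d0, 4, 1, 1)
  bn <- init_bn_state(4, 1)
  batch <- build_batch(list(g), list(enumerate_paths(g, 1)))
  fwd <- molpath_forward(par, batch, cfg, bn)
  expect_equal(fwd$H[[1]],
               g$X %*% par$W_in + matrix(par$b_in, 3, 4, byrow = TRUE))
  # zero features -> embedding is the bias row
  g0 <- g; g0$X <- g$X * 0
  b0 <- build_batch(list(g0), list(enumerate_paths(g0, 1)))
  f0 <- molpath_forward(par, b0, cfg, bn)
  expect_equal(f0$H[[1]], matrix(par$b_in, 3, 4, byrow = TRUE))
})

test_that("path encoding is direction-sensitive and local to the path", {
  set.seed(6)
  d <- 5
  lstm <- init_lstm(d)
  Htil <- matrix(rnorm(8 * d), 8, d)
  # single-node path depends only on that node's row
  e1 <- encode_path(Htil, 3L, lstm)
  Htil2 <- Htil
  Htil2[-3, ] <- rnorm(7 * d)
  expect_equal(encode_path(Htil2, 3L, lstm), e1)
  # reversed paths give different encodings in general
  fwd <- encode_path(Htil, c(1L, 2L, 3L, 4L), lstm)
  rev <- encode_path(Htil, c(4L, 3L, 2L, 1L), lstm)
  expect_gt(max(abs(fwd - rev)), 1e-6)
})

test_that("degenerate-gate limit reduces the encoder to the start node", {
  # recurrent weights zero, input/output gates saturated open, forget gate
  # saturated shut: h = tanh(tanh(Wg' x_start + bg)), an image of the start
  # node's row only
  set.seed(8)
  d <- 4
  Wg <- matrix(rnorm(d * d), d, d)
  bg <- rnorm(d)
  lstm <- list(Wx = cbind(matrix(0, d, d), matrix(0, d, d), Wg, matrix(0, d, d)),
               Wh = matrix(0, d, 4 * d),
               b = c(rep(30, d), rep(-30, d), bg, rep(30, d)))
  Htil <- matrix(rnorm(5 * d), 5, d)
  path <- c(2L, 4L, 5L)          # start node 2 consumed last
  got <- encode_path(Htil, path, lstm)
  expected <- tanh(tanh(drop(Htil[2L, ] %*% Wg) + bg))
  expect_equal(got, expected, tolerance = 1e-8)
})

test_that("nodes without length-k geodesics take the empty-sum branch", {
  # P4 with K=3: only the two end nodes have length-3 geodesics, so the
  # middle rows of H(3) must equal MLP(LayerNorm(H(2)[v])) with no path term
  g <- chain_graph(4)
  cfg <- molpath_config(K = 3, d = 6, lambda = 0.4)
  set.seed(10)
  par <- init_params(ncol(g$X), 6, 3, 1)
  bn <- init_bn_state(6, 3)
  batch <- build_batch(list(g), list(enumerate_paths(g, 3)))
  fwd <- molpath_forward(par, batch, cfg, bn)
  lp <- par$layers[[3]]
  for (v in 2:3) {
    m <- fwd$H[[3]][v, ]
    xh <- (m - mean(m)) / sqrt(mean((m - mean(m))^2) + 1e-5)
    yln <- xh * lp$ln_gamma + lp$ln_beta
    a1 <- drop(yln %*% lp$W1) + lp$b1
    hk <- drop(pmax(a1, 0) %*% lp$W2) + lp$b2
    expect_equal(fwd$H[[4]][v, ], hk, tolerance = 1e-10)
  }
})

test_that("node representations are permutation-equivariant", {
  set.seed(12)
  cfg <- molpath_config(K = 3, d = 8, lambda = 0.5)
  for (i in 1:10) {
    g <- random_connected_graph(sample(5:10, 1), 0.3)
    par <- init_params(ncol(g$X), 8, 3, 1)
    bn <- init_bn_state(8, 3)
    perm <- sample(g$n)
    gp <- permute_graph(g, perm)
    f1 <- molpath_forward(par, build_batch(list(g), list(enumerate_paths(g, 3))),
                          cfg, bn)
    f2 <- molpath_forward(par, build_batch(list(gp), list(enumerate_paths(gp, 3))),
                          cfg, bn)
    for (k in 1:4) {
      rel <- max(abs(f2$H[[k]][perm, ] - f1$H[[k]])) /
        max(1e-8, max(abs(f1$H[[k]])))
      expect_lt(rel, 1e-5)
    }
  }
})

test_that("analytic gradients match finite differences in every configuration", {
  configs <- list(
    list(task = "regression"),
    list(task = "classification"),
    list(task = "regression", use_irdc = FALSE),
    list(task = "regression", use_attention = FALSE, pool = "sum"),
    list(task = "regression", share_lstm = TRUE, attention_scale = "sqrt_d")
  )
  for (cf in configs) {
    task <- cf$task
    cf$task <- NULL
    ds <- generate_chain_molecules(
      3, c(5, 7), k_star = 3, seed = 17,
      target = if (task == "classification") "substituent_parity"
               else "distance_pair_count")
    cfg <- do.call(molpath_config, c(list(K = 3, d = 4, lambda = 0.5), cf))
    set.seed(1)
    par <- init_params(ds$d0, cfg$d, cfg$K, 1, cfg$share_lstm)
    bn <- init_bn_state(cfg$d, cfg$K)
    ps <- lapply(ds$graphs, enumerate_paths, K = cfg$K)
    batch <- build_batch(ds$graphs, ps, ds$y, ds$mask)
    lossfn <- function(p) {
      f <- molpath_forward(p, batch, cfg, bn, training = TRUE)
      loss_and_grad(f$yhat, batch$y, batch$mask, task)$loss
    }
    fwd <- molpath_forward(par, batch, cfg, bn, training = TRUE,
                           keep_cache = TRUE)
    lg <- loss_and_grad(fwd$yhat, batch$y, batch$mask, task)
    bk <- molpath_backward(par, batch, cfg, fwd, lg$dY)
    flat <- unlist(par); gflat <- unlist(bk$grads)
    idx <- sample(length(flat), 30)
    eps <- 1e-5
    num <- vapply(idx, function(i) {
      (lossfn(utils::relist(replace(flat, i, flat[i] + eps), par)) -
       lossfn(utils::relist(replace(flat, i, flat[i] - eps), par))) / (2 * eps)
    }, numeric(1))
    err <- max(abs(num - gflat[idx]) / pmax(1e-4, abs(num) + abs(gflat[idx])))
    expect_lt(err, 1e-4)
  }
})

test_that("a K-layer path model reaches nodes K hops away on a chain", {
  # long-range mechanism: perturbing the far end of a 5-chain changes the
  # representation of node 1 at layer 4
  g <- chain_graph(5)
  cfg <- molpath_config(K = 4, d = 6, lambda = 0.5)
  set.seed(14)
  par <- init_params(ncol(g$X), 6, 4, 1)
  bn <- init_bn_state(6, 4)
  base <- molpath_forward(par, build_batch(list(g), list(enumerate_paths(g, 4))),
                          cfg, bn)
  g2 <- g
  g2$X[5, ] <- g2$X[5, ] + 0.5
  pert <- molpath_forward(par, build_batch(list(g2), list(enumerate_paths(g2, 4))),
                          cfg, bn)
  expect_gt(max(abs(pert$H[[5]][1, ] - base$H[[5]][1, ])), 1e-8)
})
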