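# Path-convolution network internals.
#
# Architecture per forward pass, for a batch of molecules packed into one
# block-diagonal graph (node rows concatenated, path node indices offset):
#
#   H(0) = X W_in + b_in                                   (initial embedding)
#   for k = 1..K:
#     R      = (1-lambda) H(0) - lambda sum_{j<k} H(j)     (IRDC; or H(k-1))
#     Htil   = BatchNorm_k(R)
#     enc_p  = LSTM_k over each geodesic of length k, reversed
#              (end node first, start node last; final hidden state kept)
#     S[v]   = sum of enc_p over paths starting at v        (0 if none)
#     H(k)   = MLP_k(LayerNorm_k(S + H(k-1)))
#   omega[v, k] = softmax_k( <W_att H(0)[v], W_att H(k)[v]> / s )
#   Hg     = Pool_g( H(0) + sum_k omega[, k] * H(k) )
#   y_hat  = W2 relu(W1 Hg + b1) + b2
#
# All gradients are derived by hand and checked against finite differences
# in the test suite.

BN_EPS <- 1e-5
LN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Model configuration for the path-convolution network
#'
#' @param K number of path-convolution layers = maximum geodesic length.
#' @param d hidden width.
#' @param lambda IRDC mixing weight in (0, 1]: layer input is
#'   (1-lambda) H(0) - lambda * sum of previous layers' outputs.
#' @param dropout dropout rate inside the per-layer MLP, in \[0, 1).
#' @param pool graph pooling, `"mean"` (default, size-stable) or `"sum"`.
#' @param use_irdc `FALSE` replaces the IRDC input by the previous layer's
#'   output (ablation).
#' @param use_attention `FALSE` replaces learned hop attention by uniform
#'   1/K weights (ablation).
#' @param attention_scale divide attention scores by `"d"` (default) or
#'   `"sqrt_d"`.
#' @param share_lstm share one sequence encoder across layers instead of one
#'   per layer.
#' @return A `molpath_config` list.
#' @export
molpath_config <- function(K = 4L, d = 64L, lambda = 0.5, dropout = 0,
                           pool = c("mean", "sum"), use_irdc = TRUE,
                           use_attention = TRUE,
                           attention_scale = c("d", "sqrt_d"),
                           share_lstm = FALSE) {
  pool <- match.arg(pool)
  attention_scale <- match.arg(attention_scale)
  if (K < 1L) stop("K must be >= 1")
  if (d < 1L) stop("d must be >= 1")
  if (lambda <= 0 || lambda > 1) stop("lambda must be in (0, 1]")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(K = as.integer(K), d = as.integer(d), lambda = lambda,
                 dropout = dropout, pool = pool, use_irdc = use_irdc,
                 use_attention = use_attention,
                 attention_scale = attention_scale, share_lstm = share_lstm),
            class = "molpath_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

init_lstm <- function(d) {
  b <- numeric(4L * d)
  b[d + seq_len(d)] <- 1  # forget-gate bias 1 (standard)
  list(Wx = glorot(d, 4L * d), Wh = glorot(d, 4L * d), b = b)
}

# Parameter pytree. Layer k holds batch-norm affine, sequence encoder,
# layer-norm affine and the 2-layer MLP phi.
init_params <- function(d0, d, K, n_tasks, share_lstm = FALSE) {
  layers <- lapply(seq_len(K), function(k) {
    l <- list(bn_gamma = rep(1, d), bn_beta = numeric(d),
              ln_gamma = rep(1, d), ln_beta = numeric(d),
              W1 = glorot(d, d), b1 = numeric(d),
              W2 = glorot(d, d), b2 = numeric(d))
    if (!share_lstm || k == 1L) l$lstm <- init_lstm(d)
    l
  })
  list(W_in = glorot(d0, d), b_in = numeric(d),
       layers = layers,
       W_att = glorot(d, d),
       head = list(W1 = glorot(d, d), b1 = numeric(d),
                   W2 = glorot(d, n_tasks), b2 = numeric(n_tasks)))
}

init_bn_state <- function(d, K) {
  lapply(seq_len(K), function(k) list(mean = numeric(d), var = rep(1, d)))
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

count_params <- function(par) {
  sum(unlist(lapply(par, function(p) if (is.list(p)) count_params(p) else length(p))))
}

# ---- batch packing --------------------------------------------------------

# Pack graphs (+ their path sets) into one block-diagonal batch: node rows
# concatenated; path matrices offset into global node indices.
build_batch <- function(graphs, pathsets, y = NULL, mask = NULL) {
  K <- pathsets[[1L]]$K
  ns <- vapply(graphs, function(g) g$n, integer(1))
  offs <- cumsum(c(0L, ns[-length(ns)]))
  X <- do.call(rbind, lapply(graphs, function(g) g$X))
  graph_id <- rep(seq_along(graphs), ns)
  paths <- lapply(seq_len(K), function(k) {
    mats <- lapply(seq_along(graphs), function(i) {
      m <- pathsets[[i]]$paths[[k]]
      if (nrow(m)) m + offs[i] else m
    })
    do.call(rbind, mats)
  })
  list(X = X, graph_id = graph_id, n_per = ns, N = sum(ns),
       n_graphs = length(graphs), K = K, paths = paths, y = y, mask = mask)
}

# ---- building-block operations -------------------------------------------

#' IRDC layer input (pre-normalization)
#'
#' The initial residual difference connection: the input to layer k is
#' (1-lambda) H(0) - lambda * (H(1) + ... + H(k-1)), i.e. the initial
#' features minus the information already extracted by previous layers. At
#' k = 1 the sum is empty and the input is (1-lambda) H(0). Batch
#' normalization is applied afterwards inside the forward pass, not here.
#'
#' @param H list of node-representation matrices; `H[[1]]` is H(0) and
#'   `H[[j+1]]` is layer j's output.
#' @param k layer index (1-based, `1 <= k <= length(H) - 1` populated).
#' @param lambda mixing weight in (0, 1].
#' @param use_irdc if `FALSE`, returns `H[[k]]` (the previous layer's
#'   output) unchanged — the ablation pathway.
#' @return Matrix of the same shape as `H[[1]]`.
#' @export
irdc_input <- function(H, k, lambda, use_irdc = TRUE) {
  if (k < 1L) stop("k must be >= 1")
  if (!use_irdc) return(H[[k]])
  out <- (1 - lambda) * H[[1L]]
  if (k > 1L) {
    for (j in 2:k) out <- out - lambda * H[[j]]
  }
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Vectorised LSTM over a bucket of equal-length paths, consumed in REVERSED
# order (end node first, start node last). Returns the final hidden state
# per path and, optionally, the per-step cache for backprop.
lstm_encode <- function(Htil, Pmat, lstm, keep_cache = FALSE) {
  P <- nrow(Pmat); L <- ncol(Pmat); d <- ncol(Htil)
  h <- matrix(0, P, d); cc <- matrix(0, P, d)
  steps <- if (keep_cache) vector("list", L) else NULL
  for (t in seq_len(L)) {
    idx <- Pmat[, L + 1L - t]
    xt <- Htil[idx, , drop = FALSE]
    gates <- xt %*% lstm$Wx + h %*% lstm$Wh +
      matrix(lstm$b, P, 4L * d, byrow = TRUE)
    gi <- sigmoid(gates[, seq_len(d), drop = FALSE])
    gf <- sigmoid(gates[, d + seq_len(d), drop = FALSE])
    gg <- tanh(gates[, 2L * d + seq_len(d), drop = FALSE])
    go <- sigmoid(gates[, 3L * d + seq_len(d), drop = FALSE])
    c_prev <- cc
    cc <- gf * c_prev + gi * gg
    tc <- tanh(cc)
    h_prev <- h
    h <- go * tc
    if (keep_cache) {
      steps[[t]] <- list(idx = idx, gi = gi, gf = gf, gg = gg, go = go,
                         c_prev = c_prev, tc = tc, h_prev = h_prev)
    }
  }
  list(h = h, steps = steps)
}

#' Encode one path with the recurrent sequence encoder
#'
#' Gathers the rows of `H_tilde` along the path in reversed order (end node
#' first, start node last), runs a single-layer LSTM of the hidden width and
#' returns the final hidden state — the step that consumed the start node,
#' where the most task-relevant information is assumed to concentrate.
#'
#' @param H_tilde node representation matrix (IRDC output).
#' @param path integer vector of node indices, start node first.
#' @param lstm parameter list with `Wx` (d x 4d), `Wh` (d x 4d), `b` (4d);
#'   gate order input/forget/cell/output.
#' @return Numeric vector of length d.
#' @export
encode_path <- function(H_tilde, path, lstm) {
  out <- lstm_encode(H_tilde, matrix(as.integer(path), nrow = 1L), lstm)
  drop(out$h)
}

# Scatter-add path encodings onto their start nodes.
scatter_paths <- function(enc, starts, N) {
  agg <- matrix(0, N, ncol(enc))
  if (nrow(enc)) {
    rs <- rowsum(enc, group = starts)
    agg[as.integer(rownames(rs)), ] <- rs
  }
  agg
}

#' Attention weights over hop distances
#'
#' Per node v, the score for hop k is the inner product of the projected
#' initial feature (query) and the projected layer-k representation (key),
#' divided by the hidden width d (or sqrt(d)), then softmaxed over
#' k = 1..K. With `use_attention = FALSE` the weights are uniform 1/K.
#'
#' @param H list of K+1 node matrices (`H[[1]]` = initial embedding).
#' @param W_att shared query/key projection (d x d).
#' @param scale `"d"` or `"sqrt_d"`.
#' @param use_attention ablation flag.
#' @return Matrix n x K of nonnegative weights; each row sums to 1.
#' @export
path_attention <- function(H, W_att, scale = c("d", "sqrt_d"),
                           use_attention = TRUE) {
  scale <- match.arg(scale)
  K <- length(H) - 1L
  n <- nrow(H[[1L]]); d <- ncol(H[[1L]])
  if (!use_attention) return(matrix(1 / K, n, K))
  s <- if (scale == "d") d else sqrt(d)
  Q <- H[[1L]] %*% W_att
  scores <- vapply(seq_len(K), function(k) {
    rowSums(Q * (H[[k + 1L]] %*% W_att)) / s
  }, numeric(n))
  scores <- matrix(scores, n, K)
  m <- apply(scores, 1L, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

#' Fuse hop representations and pool to a graph vector
#'
#' Node fusion H(0)[v] + sum_k omega[v,k] H(k)[v], then a permutation-
#' invariant reduction over nodes (mean by default) per graph.
#'
#' @param H list of K+1 node matrices.
#' @param omega attention weights (n x K), e.g. from [path_attention()].
#' @param pool `"mean"` or `"sum"`.
#' @param graph_id integer vector mapping node rows to graphs (default: one
#'   graph).
#' @return List with `node_repr` (n x d fused matrix) and `H_g` (graphs x d).
#' @export
fuse_and_pool <- function(H, omega, pool = c("mean", "sum"), graph_id = NULL) {
  pool <- match.arg(pool)
  K <- length(H) - 1L
  n <- nrow(H[[1L]])
  if (is.null(graph_id)) graph_id <- rep(1L, n)
  Z <- H[[1L]]
  for (k in seq_len(K)) Z <- Z + omega[, k] * H[[k + 1L]]
  Hg <- rowsum(Z, group = graph_id)
  if (pool == "mean") {
    counts <- as.vector(table(factor(graph_id, levels = rownames(Hg))))
    Hg <- Hg / counts
  }
  list(node_repr = Z, H_g = Hg)
}

# ---- full forward pass ----------------------------------------------------

# Returns yhat plus (optionally) every intermediate needed by the backward
# pass. `bn` carries running batch-norm statistics; in training mode batch
# statistics are used and the running ones updated (returned in $bn).
molpath_forward <- function(par, batch, cfg, bn, training = FALSE,
                            keep_cache = FALSE) {
  K <- cfg$K; d <- cfg$d; N <- batch$N
  H0 <- batch$X %*% par$W_in + matrix(par$b_in, N, d, byrow = TRUE)
  H <- vector("list", K + 1L)
  H[[1L]] <- H0
  layer_cache <- if (keep_cache) vector("list", K) else NULL
  bn_out <- bn
  for (k in seq_len(K)) {
    lp <- par$layers[[k]]
    lstm <- if (cfg$share_lstm) par$layers[[1L]]$lstm else lp$lstm
    R <- irdc_input(H, k, cfg$lambda, cfg$use_irdc)
    if (training) {
      mu <- colMeans(R)
      v <- colMeans(R^2) - mu^2
      v[v < 0] <- 0
      bn_out[[k]]$mean <- (1 - BN_MOMENTUM) * bn_out[[k]]$mean + BN_MOMENTUM * mu
      bn_out[[k]]$var <- (1 - BN_MOMENTUM) * bn_out[[k]]$var + BN_MOMENTUM * v
    } else {
      mu <- bn[[k]]$mean
      v <- bn[[k]]$var
    }
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- (R - matrix(mu, N, d, byrow = TRUE)) *
      matrix(invstd, N, d, byrow = TRUE)
    Htil <- xhat * matrix(lp$bn_gamma, N, d, byrow = TRUE) +
      matrix(lp$bn_beta, N, d, byrow = TRUE)
    Pmat <- batch$paths[[k]]
    if (nrow(Pmat)) {
      le <- lstm_encode(Htil, Pmat, lstm, keep_cache = keep_cache)
      agg <- scatter_paths(le$h, Pmat[, 1L], N)
    } else {
      le <- NULL
      agg <- matrix(0, N, d)
    }
    M <- agg + H[[k]]
    mu_r <- rowMeans(M)
    var_r <- rowMeans((M - mu_r)^2)
    invstd_r <- 1 / sqrt(var_r + LN_EPS)
    xhat_ln <- (M - mu_r) * invstd_r
    Yln <- xhat_ln * matrix(lp$ln_gamma, N, d, byrow = TRUE) +
      matrix(lp$ln_beta, N, d, byrow = TRUE)
    A1 <- Yln %*% lp$W1 + matrix(lp$b1, N, d, byrow = TRUE)
    Z <- A1 * (A1 > 0)
    if (training && cfg$dropout > 0) {
      dropmask <- matrix(stats::rbinom(N * d, 1L, 1 - cfg$dropout), N, d) /
        (1 - cfg$dropout)
      Zd <- Z * dropmask
    } else {
      dropmask <- NULL
      Zd <- Z
    }
    H[[k + 1L]] <- Zd %*% lp$W2 + matrix(lp$b2, N, d, byrow = TRUE)
    if (keep_cache) {
      layer_cache[[k]] <- list(xhat_bn = xhat, invstd_bn = invstd, Htil = Htil,
                               lstm_steps = if (!is.null(le)) le$steps,
                               xhat_ln = xhat_ln, invstd_r = invstd_r,
                               Yln = Yln, A1 = A1, Zd = Zd,
                               dropmask = dropmask)
    }
  }
  omega <- path_attention(H, par$W_att, cfg$attention_scale, cfg$use_attention)
  fp <- fuse_and_pool(H, omega, cfg$pool, batch$graph_id)
  Hg <- fp$H_g
  G <- nrow(Hg)
  Ah <- Hg %*% par$head$W1 + matrix(par$head$b1, G, d, byrow = TRUE)
  Rl <- Ah * (Ah > 0)
  yhat <- Rl %*% par$head$W2 +
    matrix(par$head$b2, G, length(par$head$b2), byrow = TRUE)
  out <- list(yhat = yhat, H_g = Hg, omega = omega, H = H, bn = bn_out)
  if (keep_cache) {
    out$cache <- list(H = H, layer = layer_cache, omega = omega,
                      Hg = Hg, Ah = Ah, Rl = Rl)
  }
  out
}

# ---- full backward pass ---------------------------------------------------

lstm_backward <- function(Htil, Pmat, lstm, steps, denc, d) {
  P <- nrow(Pmat); L <- ncol(Pmat)
  gWx <- lstm$Wx * 0; gWh <- lstm$Wh * 0; gb <- lstm$b * 0
  dHtil <- Htil * 0
  dh <- denc
  dc <- matrix(0, P, d)
  for (t in L:1) {
    st <- steps[[t]]
    do_ <- dh * st$tc
    dc <- dc + dh * st$go * (1 - st$tc^2)
    di <- dc * st$gg
    dg <- dc * st$gi
    df <- dc * st$c_prev
    dc <- dc * st$gf
    dzi <- di * st$gi * (1 - st$gi)
    dzf <- df * st$gf * (1 - st$gf)
    dzg <- dg * (1 - st$gg^2)
    dzo <- do_ * st$go * (1 - st$go)
    dgates <- cbind(dzi, dzf, dzg, dzo)
    xt <- Htil[st$idx, , drop = FALSE]
    gWx <- gWx + crossprod(xt, dgates)
    gWh <- gWh + crossprod(st$h_prev, dgates)
    gb <- gb + colSums(dgates)
    dxt <- dgates %*% t(lstm$Wx)
    rs <- rowsum(dxt, group = st$idx)
    ridx <- as.integer(rownames(rs))
    dHtil[ridx, ] <- dHtil[ridx, , drop = FALSE] + rs
    dh <- dgates %*% t(lstm$Wh)
  }
  list(gWx = gWx, gWh = gWh, gb = gb, dHtil = dHtil)
}

# dY: gradient of the scalar loss wrt yhat (graphs x tasks).
molpath_backward <- function(par, batch, cfg, fwd, dY, want_dX = FALSE) {
  K <- cfg$K; d <- cfg$d; N <- batch$N
  cache <- fwd$cache
  H <- cache$H
  g <- zero_like(par)
  # head
  g$head$W2 <- crossprod(cache$Rl, dY)
  g$head$b2 <- colSums(dY)
  dRl <- dY %*% t(par$head$W2)
  dAh <- dRl * (cache$Ah > 0)
  g$head$W1 <- crossprod(cache$Hg, dAh)
  g$head$b1 <- colSums(dAh)
  dHg <- dAh %*% t(par$head$W1)
  # pooling
  if (cfg$pool == "mean") {
    dZ <- dHg[batch$graph_id, , drop = FALSE] / batch$n_per[batch$graph_id]
  } else {
    dZ <- dHg[batch$graph_id, , drop = FALSE]
  }
  # fusion + attention
  omega <- cache$omega
  dH <- lapply(seq_len(K + 1L), function(i) matrix(0, N, d))
  dH[[1L]] <- dZ
  domega <- matrix(0, N, K)
  for (k in seq_len(K)) {
    dH[[k + 1L]] <- dH[[k + 1L]] + omega[, k] * dZ
    domega[, k] <- rowSums(dZ * H[[k + 1L]])
  }
  if (cfg$use_attention) {
    ds <- omega * (domega - rowSums(domega * omega))
    s <- if (cfg$attention_scale == "d") d else sqrt(d)
    Q <- H[[1L]] %*% par$W_att
    dQ <- matrix(0, N, d)
    for (k in seq_len(K)) {
      Kk <- H[[k + 1L]] %*% par$W_att
      dQ <- dQ + ds[, k] * Kk / s
      dKk <- ds[, k] * Q / s
      g$W_att <- g$W_att + crossprod(H[[k + 1L]], dKk)
      dH[[k + 1L]] <- dH[[k + 1L]] + dKk %*% t(par$W_att)
    }
    g$W_att <- g$W_att + crossprod(H[[1L]], dQ)
    dH[[1L]] <- dH[[1L]] + dQ %*% t(par$W_att)
  }
  # layers, top down; `carry` accumulates the -lambda dR IRDC terms owed to
  # every earlier layer's output (and (1-lambda) dR owed to H0).
  carry <- matrix(0, N, d)
  dH0_extra <- matrix(0, N, d)
  for (k in K:1) {
    lp <- par$layers[[k]]
    lc <- cache$layer[[k]]
    dHk <- dH[[k + 1L]] + carry
    # MLP
    g$layers[[k]]$W2 <- crossprod(lc$Zd, dHk)
    g$layers[[k]]$b2 <- colSums(dHk)
    dZd <- dHk %*% t(lp$W2)
    dZr <- if (is.null(lc$dropmask)) dZd else dZd * lc$dropmask
    dA1 <- dZr * (lc$A1 > 0)
    g$layers[[k]]$W1 <- crossprod(lc$Yln, dA1)
    g$layers[[k]]$b1 <- colSums(dA1)
    dYln <- dA1 %*% t(lp$W1)
    # layer norm
    g$layers[[k]]$ln_gamma <- colSums(dYln * lc$xhat_ln)
    g$layers[[k]]$ln_beta <- colSums(dYln)
    dxh <- dYln * matrix(lp$ln_gamma, N, d, byrow = TRUE)
    dM <- lc$invstd_r *
      (dxh - rowMeans(dxh) - lc$xhat_ln * rowMeans(dxh * lc$xhat_ln))
    # residual
    dH[[k]] <- dH[[k]] + dM
    # paths
    Pmat <- batch$paths[[k]]
    if (nrow(Pmat)) {
      denc <- dM[Pmat[, 1L], , drop = FALSE]
      lstm <- if (cfg$share_lstm) par$layers[[1L]]$lstm else lp$lstm
      lb <- lstm_backward(lc$Htil, Pmat, lstm, lc$lstm_steps, denc, d)
      tgt <- if (cfg$share_lstm) 1L else k
      g$layers[[tgt]]$lstm$Wx <- g$layers[[tgt]]$lstm$Wx + lb$gWx
      g$layers[[tgt]]$lstm$Wh <- g$layers[[tgt]]$lstm$Wh + lb$gWh
      g$layers[[tgt]]$lstm$b <- g$layers[[tgt]]$lstm$b + lb$gb
      dHtil <- lb$dHtil
    } else {
      dHtil <- matrix(0, N, d)
    }
    # batch norm
    g$layers[[k]]$bn_gamma <- colSums(dHtil * lc$xhat_bn)
    g$layers[[k]]$bn_beta <- colSums(dHtil)
    dxb <- dHtil * matrix(lp$bn_gamma, N, d, byrow = TRUE)
    if (N > 0L) {
      dR <- matrix(lc$invstd_bn, N, d, byrow = TRUE) *
        (dxb -
           matrix(colMeans(dxb), N, d, byrow = TRUE) -
           lc$xhat_bn * matrix(colMeans(dxb * lc$xhat_bn), N, d, byrow = TRUE))
    } else {
      dR <- dxb
    }
    # IRDC distribution
    if (cfg$use_irdc) {
      dH0_extra <- dH0_extra + (1 - cfg$lambda) * dR
      carry <- carry - cfg$lambda * dR
      if (k == 1L) carry <- matrix(0, N, d)
    } else {
      dH[[k]] <- dH[[k]] + dR
      carry <- carry * 0
    }
  }
  dH0 <- dH[[1L]] + dH0_extra
  g$W_in <- crossprod(batch$X, dH0)
  g$b_in <- colSums(dH0)
  out <- list(grads = g)
  if (want_dX) out$dX <- dH0 %*% t(par$W_in)
  out
}

# ---- Adam -----------------------------------------------------------------

adam_state <- function(par) list(m = zero_like(par), v = zero_like(par), t = 0L)

adam_step <- function(par, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  t <- st$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in seq_along(p)) {
        if (is.null(g[[nm]])) next
        r <- rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g^2
    mhat <- m2 / (1 - beta1^t)
    vhat <- v2 / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
  }
  r <- rec(par, grads, st$m, st$v)
  st$m <- r$m; st$v <- r$v
  list(par = r$p, state = st)
}
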