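#' Fit a chain-aware path-convolution network
#'
#' Trains the path-convolution model on a labelled molecular dataset: K
#' layers of convolution along exact-length shortest paths with IRDC inputs,
#' an LSTM path encoder, attention over hop distances and a 2-layer
#' prediction head. Classification tasks use masked binary cross-entropy on
#' logits; regression tasks use the L1 loss on standardized targets.
#' Optimisation is Adam with minibatches; model selection keeps the
#' parameters from the best validation epoch (lowest RMSE / highest mean
#' ROC-AUC), with patience-based early stopping.
#'
#' @param data training [molpath_dataset()].
#' @param valid optional validation dataset for model selection; without it
#'   the final epoch's parameters are kept.
#' @param K number of path-convolution layers (= max geodesic length).
#' @param hidden hidden width d.
#' @param lambda IRDC mixing weight in (0, 1].
#' @param dropout dropout rate in the per-layer MLPs.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size (number of molecules).
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement); ignored without `valid`.
#' @param pool,use_irdc,use_attention,attention_scale,share_lstm see
#'   [molpath_config()].
#' @param seed root seed for parameter initialisation, shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return An object of class `molpath`: parameters, config, batch-norm
#'   state, training `history` (data frame of epoch, train loss, validation
#'   metric), `best_epoch`, task metadata and target standardisation.
#' @seealso [predict.molpath()], [run_ablation()], [generate_chain_molecules()]
#' @export
molpath <- function(data, valid = NULL, K = 4L, hidden = 64L, lambda = 0.5,
                    dropout = 0, lr = 1e-3, batch_size = 32L, epochs = 100L,
                    patience = 30L, pool = "mean", use_irdc = TRUE,
                    use_attention = TRUE, attention_scale = "d",
                    share_lstm = FALSE, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(data, "molpath_dataset"))
  cfg <- molpath_config(K = K, d = hidden, lambda = lambda, dropout = dropout,
                        pool = pool, use_irdc = use_irdc,
                        use_attention = use_attention,
                        attention_scale = attention_scale,
                        share_lstm = share_lstm)
  warn_range <- function(x, lo, hi, nm) {
    if (x < lo || x > hi) {
      warning(sprintf("%s = %s is outside the usual range [%s, %s]",
                      nm, format(x), format(lo), format(hi)))
    }
  }
  warn_range(lambda, 1e-12, 0.6, "lambda")
  n_tasks <- ncol(data$y)
  task_type <- data$task_type

  pathsets <- lapply(data$graphs, enumerate_paths, K = cfg$K)
  valid_pathsets <- if (!is.null(valid)) {
    lapply(valid$graphs, enumerate_paths, K = cfg$K)
  }

  # standardize regression targets on the labelled training entries
  y_center <- 0; y_scale <- 1
  y_train <- data$y
  if (task_type == "regression") {
    obs <- data$y[data$mask]
    y_center <- mean(obs)
    y_scale <- stats::sd(obs)
    if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
    y_train <- (data$y - y_center) / y_scale
  }

  with_seed(seed, {
    par <- init_params(data$d0, cfg$d, cfg$K, n_tasks, cfg$share_lstm)
    bn <- init_bn_state(cfg$d, cfg$K)
    opt <- adam_state(par)
    N <- length(data$graphs)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          valid_metric = numeric(0))
    best_metric <- if (task_type == "regression") Inf else -Inf
    best_par <- par; best_bn <- bn; best_epoch <- 0L; stall <- 0L
    vb <- if (!is.null(valid)) {
      build_batch(valid$graphs, valid_pathsets, valid$y, valid$mask)
    }
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(N)
      nb <- max(1L, ceiling(N / batch_size))
      ep_loss <- 0; ep_n <- 0
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, N)]
        batch <- build_batch(data$graphs[idx], pathsets[idx],
                             y_train[idx, , drop = FALSE],
                             data$mask[idx, , drop = FALSE])
        fwd <- molpath_forward(par, batch, cfg, bn, training = TRUE,
                               keep_cache = TRUE)
        bn <- fwd$bn
        lg <- loss_and_grad(fwd$yhat, batch$y, batch$mask, task_type)
        if (!is.finite(lg$loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
        }
        bk <- molpath_backward(par, batch, cfg, fwd, lg$dY)
        st <- adam_step(par, bk$grads, opt, lr)
        par <- st$par; opt <- st$state
        ep_loss <- ep_loss + lg$loss * length(idx); ep_n <- ep_n + length(idx)
      }
      vm <- NA_real_
      if (!is.null(valid)) {
        pv <- molpath_forward(par, vb, cfg, bn, training = FALSE)$yhat
        if (task_type == "regression") {
          vm <- rmse(pv * y_scale + y_center, valid$y, valid$mask)
          improved <- vm < best_metric
        } else {
          vm <- suppressWarnings(roc_auc(pv, valid$y, valid$mask)$mean_auc)
          improved <- vm > best_metric
        }
        if (improved) {
          best_metric <- vm; best_par <- par; best_bn <- bn
          best_epoch <- epoch; stall <- 0L
        } else {
          stall <- stall + 1L
        }
      }
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = ep_loss / ep_n,
                                           valid_metric = vm))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  valid %.4f", epoch,
                        ep_loss / ep_n, vm))
      }
      if (!is.null(valid) && stall >= patience) break
    }
    if (is.null(valid)) {
      best_par <- par; best_bn <- bn; best_epoch <- nrow(history)
      best_metric <- NA_real_
    }
    structure(
      list(par = best_par, bn = best_bn, config = cfg,
           task_type = task_type, task_names = data$task_names,
           n_tasks = n_tasks, d0 = data$d0,
           y_center = y_center, y_scale = y_scale,
           history = history, best_epoch = best_epoch,
           best_valid_metric = best_metric,
           seed = seed, lr = lr, batch_size = batch_size,
           train_data = data, call = match.call()),
      class = "molpath"
    )
  })
}

# Loss value and gradient wrt yhat, masked, averaged over labelled entries.
loss_and_grad <- function(yhat, y, mask, task_type) {
  m <- mask & !is.na(y)
  nm <- sum(m)
  if (nm == 0L) stop("batch contains no labelled entries")
  dY <- yhat * 0
  if (task_type == "classification") {
    loss <- bce_loss(yhat[m], y[m])
    dY[m] <- (sigmoid(yhat[m]) - y[m]) / nm
  } else {
    loss <- l1_loss(yhat[m], y[m])
    dY[m] <- sign(yhat[m] - y[m]) / nm
  }
  list(loss = loss, dY = dY)
}

coerce_graphs <- function(newdata, d0) {
  if (inherits(newdata, "molpath_dataset")) return(newdata$graphs)
  if (inherits(newdata, "molecule_graph")) return(list(newdata))
  if (is.character(newdata)) return(lapply(newdata, smiles_to_graph))
  if (is.list(newdata)) return(newdata)
  stop("newdata must be a dataset, graph list, graph, or SMILES vector")
}

#' Predict molecular properties from a fitted model
#'
#' @param object a fitted [molpath()] model.
#' @param newdata a [molpath_dataset()], list of graphs, single
#'   [molecule_graph()], or character vector of SMILES.
#' @param type `"response"` (default: probabilities for classification,
#'   original-scale values for regression) or `"link"` (raw logits /
#'   standardized outputs).
#' @param ... unused.
#' @return Numeric matrix, molecules x tasks.
#' @export
predict.molpath <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  graphs <- coerce_graphs(newdata, object$d0)
  pathsets <- lapply(graphs, enumerate_paths, K = object$config$K)
  batch <- build_batch(graphs, pathsets)
  out <- molpath_forward(object$par, batch, object$config, object$bn,
                         training = FALSE)$yhat
  colnames(out) <- object$task_names
  if (type == "link") return(out)
  if (object$task_type == "classification") {
    sigmoid(out)
  } else {
    out * object$y_scale + object$y_center
  }
}

#' Evaluate a fitted model on a labelled dataset
#'
#' @param object fitted [molpath()] model.
#' @param data a labelled [molpath_dataset()].
#' @return List with the task-appropriate metric: `rmse` and `l1`
#'   (regression) or `mean_auc` and `per_task` (classification).
#' @export
evaluate_molpath <- function(object, data) {
  if (object$task_type == "regression") {
    p <- predict(object, data)
    list(rmse = rmse(p, data$y, data$mask), l1 = l1_loss(p, data$y, data$mask))
  } else {
    p <- predict(object, data, type = "link")
    suppressWarnings(roc_auc(p, data$y, data$mask))
  }
}

#' @export
print.molpath <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Chain-aware path-convolution model (%s, %d task%s)\n",
              x$task_type, x$n_tasks, if (x$n_tasks > 1) "s" else ""))
  cat(sprintf("  K = %d layers, hidden = %d, lambda = %.2f, pool = %s\n",
              cfg$K, cfg$d, cfg$lambda, cfg$pool))
  if (!cfg$use_irdc) cat("  [ablation] IRDC disabled\n")
  if (!cfg$use_attention) cat("  [ablation] hop attention disabled (uniform 1/K)\n")
  cat(sprintf("  trained %d epoch(s); best validation epoch %d (%s = %s)\n",
              nrow(x$history), x$best_epoch,
              if (x$task_type == "regression") "RMSE" else "ROC-AUC",
              format(x$best_valid_metric, digits = 4)))
  invisible(x)
}

#' @export
summary.molpath <- function(object, ...) {
  out <- list(config = object$config,
              n_params = count_params(object$par),
              history = object$history,
              best_epoch = object$best_epoch,
              best_valid_metric = object$best_valid_metric,
              task_type = object$task_type)
  class(out) <- "summary.molpath"
  out
}

#' @export
print.summary.molpath <- function(x, ...) {
  cat(sprintf("Path-convolution network: %d trainable parameters\n", x$n_params))
  cat(sprintf("  K = %d, hidden = %d, lambda = %.2f\n",
              x$config$K, x$config$d, x$config$lambda))
  cat(sprintf("  best validation epoch: %d (%s = %s)\n", x$best_epoch,
              if (x$task_type == "regression") "RMSE" else "ROC-AUC",
              format(x$best_valid_metric, digits = 4)))
  cat(sprintf("  final training loss: %s\n",
              format(utils::tail(x$history$train_loss, 1), digits = 4)))
  invisible(x)
}

#' @export
coef.molpath <- function(object, ...) object$par

#' @export
residuals.molpath <- function(object, data = NULL, ...) {
  if (is.null(data)) data <- object$train_data
  if (object$task_type != "regression") {
    stop("residuals are defined for regression fits")
  }
  r <- data$y - predict(object, data)
  r[!data$mask] <- NA
  r
}

#' @export
#' @method plot molpath
plot.molpath <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, if (any(is.finite(h$valid_metric))) 2 else 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "Training loss", ...)
  if (any(is.finite(h$valid_metric))) {
    graphics::plot(h$epoch, h$valid_metric, type = "l", xlab = "epoch",
                   ylab = if (x$task_type == "regression") "validation RMSE"
                          else "validation ROC-AUC",
                   main = "Validation metric", ...)
    graphics::abline(v = x$best_epoch, lty = 2)
  }
  invisible(x)
}
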