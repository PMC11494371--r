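test_that("binary cross-entropy matches closed forms and honours the mask", {
  expect_equal(bce_loss(0, 1), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(40, 1), 1e-10)          # saturated correct logit
  expect_equal(bce_loss(c(1.3, 99), c(1, 0), mask = c(TRUE, FALSE)),
               bce_loss(1.3, 1), tolerance = 1e-12)
  expect_error(bce_loss(1, 1, mask = FALSE), "no labelled entries")
})

test_that("stabilized BCE equals the naive sigmoid formula on moderate logits", {
  set.seed(4)
  for (i in 1:20) {
    z <- runif(10, -10, 10)
    y <- rbinom(10, 1, 0.5)
    naive <- -mean(y * log(sigmoid(z)) + (1 - y) * log(1 - sigmoid(z)))
    expect_equal(bce_loss(z, y), naive, tolerance = 1e-6)
  }
})

test_that("L1 and RMSE match their closed forms", {
  expect_equal(l1_loss(3, 2), 1)
  expect_equal(l1_loss(c(5, 5), c(5, 5)), 0)
  expect_equal(l1_loss(c(0, 4), c(1, 1)), 2)       # (1 + 3) / 2
  expect_equal(rmse(c(0, 4), c(1, 1)), sqrt(5))    # sqrt((1 + 9)/2)
  expect_equal(rmse(c(1, 2, NA), c(1, 1, 1)), sqrt(0.5))
})

test_that("rank-based ROC-AUC equals brute-force pair counting", {
  expect_equal(roc_auc(c(0.1, 0.9, 0.2, 0.8), c(0, 1, 0, 1))$mean_auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$mean_auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))$mean_auc, 0.75)
  set.seed(8)
  for (n in 2:8) {
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # with ties
    for (rep in 1:10) {
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      expect_equal(roc_auc(scores, y)$mean_auc, oracle_auc(scores, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("ROC-AUC agrees with pROC and skips single-class tasks", {
  set.seed(10)
  scores <- rnorm(40)
  y <- rbinom(40, 1, 0.4)
  mine <- roc_auc(scores, y)$mean_auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)

  y2 <- cbind(y, rep(1, 40))                # second task single-class
  s2 <- cbind(scores, rnorm(40))
  expect_warning(res <- roc_auc(s2, y2), "single class")
  expect_equal(res$mean_auc, mine)          # degenerate task excluded
  expect_true(is.na(res$per_task[2]))
})

test_that("training is deterministic given the seed", {
  ds <- tiny_regression_data(6, seed = 2)
  f1 <- molpath(ds, K = 2, hidden = 8, epochs = 2, batch_size = 3, seed = 7)
  f2 <- molpath(ds, K = 2, hidden = 8, epochs = 2, batch_size = 3, seed = 7)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(unlist(f1$par), unlist(f2$par))
})

test_that("zero learning rate freezes the loss", {
  ds <- tiny_regression_data(6, seed = 2)
  f <- molpath(ds, K = 2, hidden = 8, epochs = 4, batch_size = 10, lr = 0,
               seed = 7)
  expect_equal(diff(range(f$history$train_loss)), 0, tolerance = 1e-12)
})

test_that("training loss decreases on a learnable fixture", {
  ds <- tiny_regression_data(8, seed = 3)
  f <- molpath(ds, K = 3, hidden = 16, epochs = 30, batch_size = 8, lr = 3e-3,
               seed = 1)
  h <- f$history$train_loss
  expect_lt(mean(tail(h, 5)), 0.5 * mean(head(h, 3)))
  # model selection bookkeeping with a validation set
  va <- tiny_regression_data(4, seed = 4)
  fv <- molpath(ds, valid = va, K = 2, hidden = 8, epochs = 5, batch_size = 8,
                seed = 1)
  expect_true(fv$best_epoch >= 1 && fv$best_epoch <= 5)
  expect_equal(fv$best_valid_metric,
               min(fv$history$valid_metric, na.rm = TRUE))
  ev <- evaluate_molpath(fv, va)
  expect_true(is.finite(ev$rmse) && ev$rmse >= 0)
})

test_that("masked labels never reach the loss or metrics", {
  ds <- tiny_regression_data(6, seed = 5)
  y <- ds$y
  y[2, 1] <- NA
  dsm <- molpath_dataset(ds$graphs, y, "regression")
  fit <- molpath(dsm, K = 2, hidden = 8, epochs = 3, batch_size = 6, seed = 1)
  expect_true(all(is.finite(fit$history$train_loss)))
  p <- predict(fit, dsm)
  expect_equal(rmse(p, dsm$y, dsm$mask),
               rmse(p[-2, ], dsm$y[-2, ]), tolerance = 1e-12)
})

test_that("fitted-model methods expose the usual surface", {
  ds <- tiny_regression_data(6, seed = 6)
  fit <- molpath(ds, K = 2, hidden = 8, epochs = 2, batch_size = 3, seed = 1)
  expect_output(print(fit), "path-convolution")
  expect_output(print(summary(fit)), "trainable parameters")
  expect_type(coef(fit), "list")
  r <- residuals(fit)
  expect_equal(dim(r), dim(ds$y))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  # predict from SMILES directly
  p <- predict(fit, c("CCCC", "CCCCCC"))
  expect_equal(dim(p), c(2L, 1L))
})

test_that("ablation and sweep drivers produce comparable reports", {
  tr <- tiny_regression_data(10, seed = 8)
  va <- tiny_regression_data(4, seed = 9)
  ab <- run_ablation(tr, va, K = 2, hidden = 8, epochs = 2, batch_size = 5,
                     seed = 3)
  expect_equal(ab$summary$variant, c("full", "no_irdc", "no_attention"))
  # ablation flags change computation only, never the parameter count
  expect_equal(length(unique(ab$summary$n_params)), 1L)
  expect_true(all(is.finite(ab$summary$best_valid_metric)))

  sw <- lambda_sweep(tr, va, lambdas = c(0.2, 0.5), K = 2, hidden = 8,
                     epochs = 2, batch_size = 5, seed = 3)
  expect_equal(nrow(sw), 2L)
  expect_true(all(is.finite(sw$best_valid_metric)))

  fs <- fit_seeds(tr, va, va, seeds = 1:2, K = 2, hidden = 8, epochs = 2,
                  batch_size = 5)
  expect_equal(nrow(fs$per_seed), 2L)
  expect_true(is.finite(fs$mean) && is.finite(fs$sd))
})
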