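#' Fit ablated model variants under identical conditions
#'
#' Trains the full model and its ablations — `"no_irdc"` (layer inputs are
#' the previous layer's output instead of the initial residual difference)
#' and `"no_attention"` (uniform 1/K hop weights) — with the same data,
#' seed and hyperparameters, so the reports are directly comparable. The
#' ablation flags change only the targeted computation; parameter counts are
#' identical across variants.
#'
#' @param data training [molpath_dataset()].
#' @param valid validation dataset.
#' @param variants subset of `c("full", "no_irdc", "no_attention")`.
#' @param ... further arguments passed to [molpath()] (K, hidden, ...).
#' @param seed shared seed for every variant.
#' @return List with `fits` (named list of `molpath` objects) and `summary`
#'   (data frame: variant, parameter count, best validation metric).
#' @export
run_ablation <- function(data, valid, variants = c("full", "no_irdc",
                                                   "no_attention"),
                         ..., seed = 1L) {
  variants <- match.arg(variants, several.ok = TRUE)
  fits <- lapply(variants, function(v) {
    molpath(data, valid = valid, ...,
            use_irdc = v != "no_irdc",
            use_attention = v != "no_attention",
            seed = seed)
  })
  names(fits) <- variants
  summary <- data.frame(
    variant = variants,
    n_params = vapply(fits, function(f) count_params(f$par), numeric(1)),
    best_valid_metric = vapply(fits, function(f) f$best_valid_metric,
                               numeric(1))
  )
  list(fits = fits, summary = summary)
}

#' Sweep the IRDC mixing weight lambda
#'
#' Refits the model for each lambda value under an identical seed and data,
#' reporting the best validation metric per value.
#'
#' @param data training dataset.
#' @param valid validation dataset.
#' @param lambdas values to sweep (default 0.1 .. 0.6).
#' @param ... passed to [molpath()].
#' @param seed shared seed.
#' @return Data frame with `lambda` and `best_valid_metric`; the fitted
#'   models are attached as `attr(, "fits")`.
#' @export
lambda_sweep <- function(data, valid, lambdas = seq(0.1, 0.6, by = 0.1),
                         ..., seed = 1L) {
  fits <- lapply(lambdas, function(l) {
    molpath(data, valid = valid, lambda = l, ..., seed = seed)
  })
  out <- data.frame(
    lambda = lambdas,
    best_valid_metric = vapply(fits, function(f) f$best_valid_metric,
                               numeric(1))
  )
  attr(out, "fits") <- fits
  out
}

#' Repeat a fit over several seeds and summarise
#'
#' The repeated-runs protocol: train once per seed, evaluate on a held-out
#' set, and report mean and standard deviation of the metric.
#'
#' @param data training dataset.
#' @param valid validation dataset.
#' @param test evaluation dataset.
#' @param seeds integer vector of seeds.
#' @param ... passed to [molpath()].
#' @return List with `per_seed` (data frame) and `mean`, `sd` of the test
#'   metric (RMSE for regression, mean ROC-AUC for classification).
#' @export
fit_seeds <- function(data, valid, test, seeds = 1:4, ...) {
  vals <- vapply(seeds, function(s) {
    fit <- molpath(data, valid = valid, ..., seed = s)
    ev <- evaluate_molpath(fit, test)
    if (fit$task_type == "regression") ev$rmse else ev$mean_auc
  }, numeric(1))
  list(per_seed = data.frame(seed = seeds, metric = vals),
       mean = mean(vals), sd = stats::sd(vals))
}
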