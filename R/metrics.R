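#' Masked binary cross-entropy on logits
#'
#' Mean over label-present entries of the sigmoid cross-entropy
#' -(y log p + (1-y) log(1-p)), computed in the numerically stable
#' log-sum-exp form max(z,0) - z y + log(1 + exp(-|z|)).
#'
#' @param logits numeric matrix (or vector) of raw scores.
#' @param y matching 0/1 labels.
#' @param mask optional logical matrix; `FALSE` entries are excluded.
#' @return Scalar loss.
#' @examples
#' bce_loss(0, 1)       # log(2)
#' @export
bce_loss <- function(logits, y, mask = NULL) {
  z <- as.numeric(logits); yy <- as.numeric(y)
  m <- if (is.null(mask)) rep(TRUE, length(z)) else as.logical(mask)
  m <- m & !is.na(yy)
  if (!any(m)) stop("bce_loss: no labelled entries under the mask")
  z <- z[m]; yy <- yy[m]
  mean(pmax(z, 0) - z * yy + log1p(exp(-abs(z))))
}

#' Mean absolute error (L1 loss)
#'
#' @param y_hat predictions.
#' @param y targets.
#' @param mask optional logical mask.
#' @return Scalar mean of |y - y_hat| over (masked-in) entries.
#' @export
l1_loss <- function(y_hat, y, mask = NULL) {
  e <- abs(as.numeric(y) - as.numeric(y_hat))
  m <- if (is.null(mask)) !is.na(e) else (as.logical(mask) & !is.na(e))
  if (!any(m)) stop("l1_loss: no entries")
  mean(e[m])
}

#' Root mean squared error
#'
#' @inheritParams l1_loss
#' @return Scalar sqrt(mean((y - y_hat)^2)).
#' @export
rmse <- function(y_hat, y, mask = NULL) {
  e <- (as.numeric(y) - as.numeric(y_hat))^2
  m <- if (is.null(mask)) !is.na(e) else (as.logical(mask) & !is.na(e))
  if (!any(m)) stop("rmse: no entries")
  sqrt(mean(e[m]))
}

# Rank-based (Mann-Whitney) AUC for one task; ties count 0.5.
auc_one <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged ROC-AUC over (possibly masked) tasks
#'
#' Rank-based AUC per task (tied scores contribute 0.5), then the arithmetic
#' mean over tasks with both classes present. Single-class tasks are skipped
#' with a warning and excluded from the average.
#'
#' @param scores numeric matrix (or vector) of scores, molecules x tasks.
#' @param y matching 0/1 labels.
#' @param mask optional logical mask of labelled entries.
#' @return List with `mean_auc` and `per_task`; `mean_auc` is also returned
#'   when the result is used as a scalar via `$mean_auc`.
#' @export
roc_auc <- function(scores, y, mask = NULL) {
  scores <- as.matrix(scores); y <- as.matrix(y)
  if (is.null(mask)) mask <- !is.na(y)
  per <- vapply(seq_len(ncol(y)), function(j) {
    m <- mask[, j] & !is.na(y[, j])
    if (!any(m)) return(NA_real_)
    auc_one(scores[m, j], y[m, j])
  }, numeric(1))
  if (anyNA(per)) {
    warning(sum(is.na(per)), " task(s) with a single class skipped in ROC-AUC")
  }
  list(mean_auc = mean(per, na.rm = TRUE), per_task = per)
}
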