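# Regression and classification metrics for affinity prediction.

#' Mean squared error
#'
#' @param y_true,y_pred equal-length numeric vectors.
#' @return mean of squared residuals.
#' @export
mse <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  mean((y_true - y_pred)^2)
}

#' Concordance index
#'
#' Fraction of comparable pairs (`y_x > y_y`) whose predictions are ordered
#' the same way, counting exact prediction ties as 1/2:
#' `CI = (1/Z) * sum over y_x > y_y of h(yhat_x - yhat_y)` with
#' `h = 1 / 0.5 / 0` for positive / zero / negative arguments and `Z` the
#' number of comparable pairs.
#'
#' @param y_true,y_pred equal-length numeric vectors, at least two records
#'   with differing `y_true`.
#' @return CI in `[0, 1]`.
#' @export
concordance_index <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  n <- length(y_true)
  if (n < 2L) stop_hetdta("concordance index needs at least two records")
  dy <- outer(y_true, y_true, "-")
  comp <- dy > 0
  Z <- sum(comp)
  if (Z == 0L) stop_hetdta("all y_true equal: concordance index undefined")
  dp <- outer(y_pred, y_pred, "-")
  h <- (dp > 0) + 0.5 * (dp == 0)
  sum(h[comp]) / Z
}

#' Modified squared correlation (rm-squared)
#'
#' `rm2 = r2 * (1 - sqrt(r2 - r02))` where `r2` is the squared Pearson
#' correlation (regression with intercept) and `r02` the squared coefficient
#' of the through-origin regression of predictions on observations, clamped
#' to `[0, r2]`. `formula = "paper"` uses the radicand without the square
#' root, `r2 * (1 - (r2 - r02))`.
#'
#' @param y_true,y_pred numeric vectors (length >= 3, both non-constant).
#' @param formula `"sqrt"` (literature convention, default) or `"paper"`.
#' @return rm-squared; 1 for a perfect prediction.
#' @export
rm2 <- function(y_true, y_pred, formula = c("sqrt", "paper")) {
  formula <- match.arg(formula)
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) < 3L) stop_hetdta("rm2 needs at least three records")
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0)
    stop_hetdta("rm2 undefined for constant observations or predictions")
  r2 <- stats::cor(y_true, y_pred)^2
  # through-origin fit of predictions on observations:
  # slope k = sum(y*yhat)/sum(y^2); r02 = 1 - SS_res0 / SS_tot(yhat)
  k <- sum(y_true * y_pred) / sum(y_true^2)
  ss_res0 <- sum((y_pred - k * y_true)^2)
  ss_tot <- sum((y_pred - mean(y_pred))^2)
  r02 <- 1 - ss_res0 / ss_tot
  r02 <- min(max(r02, 0), r2)
  rad <- r2 - r02
  if (rad < 0) {
    warning("negative radicand clamped to 0 in rm2")
    rad <- 0
  }
  if (formula == "sqrt") r2 * (1 - sqrt(rad)) else r2 * (1 - rad)
}

#' Classification metrics at a decision threshold
#'
#' Precision, recall, F1 at the given probability threshold, plus AUROC
#' (via `pROC`) and area under the precision-recall curve (step-wise
#' integration over unique score cut-offs).
#'
#' @param y_true 0/1 labels.
#' @param y_prob predicted probabilities in `[0, 1]`.
#' @param threshold decision threshold, default 0.5.
#' @return named list: `precision`, `recall`, `f1`, `auroc`, `aupr`.
#' @export
classification_metrics <- function(y_true, y_prob, threshold = 0.5) {
  stopifnot(length(y_true) == length(y_prob), all(y_true %in% c(0, 1)))
  pred <- as.integer(y_prob >= threshold)
  tp <- sum(pred == 1 & y_true == 1)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) NA_real_
        else 2 * precision * recall / (precision + recall)
  auroc <- as.numeric(pROC::auc(pROC::roc(y_true, y_prob, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
  list(precision = precision, recall = recall, f1 = f1,
       auroc = auroc, aupr = aupr(y_true, y_prob))
}

# area under the precision-recall curve by step integration over descending
# unique score thresholds (average-precision form)
aupr <- function(y_true, y_prob) {
  o <- order(y_prob, decreasing = TRUE)
  y <- y_true[o]; s <- y_prob[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- c(diff(s) != 0, TRUE)  # evaluate at the last index of tied scores
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y_true)
  sum(diff(c(0, rec)) * prec)
}

#' Metric report for a prediction set
#'
#' @param y_true,y_pred observed and predicted values.
#' @param task `"regression"` or `"classification"`.
#' @param rm2_formula passed to [rm2()].
#' @return named list of task-appropriate metrics plus `n`.
#' @export
metric_report <- function(y_true, y_pred, task = c("regression", "classification"),
                          rm2_formula = "sqrt") {
  task <- match.arg(task)
  if (task == "regression") {
    list(mse = mse(y_true, y_pred),
         ci = concordance_index(y_true, y_pred),
         rm2 = tryCatch(rm2(y_true, y_pred, rm2_formula),
                        error = function(e) NA_real_),
         n = length(y_true))
  } else {
    c(classification_metrics(y_true, y_pred), list(n = length(y_true)))
  }
}

#' Top-percentile prediction-error report
#'
#' Flags records whose absolute error exceeds the given percentile of the
#' absolute-error distribution (strictly greater, so an all-ties error
#' vector flags nothing) and groups them by drug and by protein with
#' per-group mean absolute error — the grouping used to trace whether large
#' errors concentrate on particular compounds or targets.
#'
#' @param drug_id,protein_id,y_true,y_pred aligned vectors.
#' @param percentile percentile of `|error|` used as the threshold (default 95).
#' @return list with `threshold`, `outliers` (flagged records, largest error
#'   first), `by_drug`, `by_protein` (group summaries).
#' @export
outlier_report <- function(drug_id, protein_id, y_true, y_pred, percentile = 95) {
  err <- abs(y_true - y_pred)
  thr <- stats::quantile(err, percentile / 100, names = FALSE)
  flag <- err > thr
  out <- data.frame(drug_id = drug_id[flag], protein_id = protein_id[flag],
                    y_true = y_true[flag], y_pred = y_pred[flag],
                    abs_error = err[flag])
  out <- out[order(-out$abs_error), , drop = FALSE]
  rownames(out) <- NULL
  grp <- function(key) {
    if (!nrow(out)) return(data.frame(id = character(0), n = integer(0),
                                      mean_abs_error = numeric(0)))
    ag <- stats::aggregate(out$abs_error, list(id = out[[key]]),
                           function(v) c(n = length(v), mae = mean(v)))
    data.frame(id = ag$id, n = as.integer(ag$x[, "n"]),
               mean_abs_error = ag$x[, "mae"])[order(-ag$x[, "mae"]), ]
  }
  list(threshold = thr, mean_abs_error = mean(err),
       outlier_mean_abs_error = if (any(flag)) mean(err[flag]) else NA_real_,
       outliers = out, by_drug = grp("drug_id"), by_protein = grp("protein_id"))
}
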