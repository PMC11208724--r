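# Performance indexes for the regression and classification tasks.

#' Regression metrics: squared Pearson correlation and RMSE
#'
#' @param y_true,y_pred Numeric vectors of equal length (>= 2).
#' @return A tibble with columns `r2` (squared Pearson correlation;
#'   `NA` when either vector has zero variance) and `rmse`.
#' @examples
#' regression_metrics(c(1, 2, 3, 4), c(1, 2, 3, 5))
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  r2 <- if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) NA_real_
        else stats::cor(y_true, y_pred)^2
  tibble::tibble(r2 = r2, rmse = sqrt(mean((y_true - y_pred)^2)))
}

#' Classification metrics
#'
#' AUROC, accuracy, Matthews correlation coefficient, specificity and
#' sensitivity. Confusion-matrix metrics threshold the score at 0.5
#' (scores are probabilities). AUROC and MCC require both classes.
#'
#' @param y_true Binary labels (0/1).
#' @param scores Predicted probabilities of class 1.
#' @return A tibble with columns `auroc`, `acc`, `mcc`, `specificity`,
#'   `sensitivity`.
#' @export
classification_metrics <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  y <- as.integer(y_true)
  stopifnot(all(y %in% c(0L, 1L)))
  both <- length(unique(y)) == 2
  auroc <- if (both) {
    as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE, direction = "<")))
  } else NA_real_
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  acc <- (tp + tn) / length(y)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (both && denom > 0) (tp * tn - fp * fn) / denom else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tibble::tibble(auroc = auroc, acc = acc, mcc = mcc,
                 specificity = spec, sensitivity = sens)
}
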