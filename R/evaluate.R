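# Evaluation surfaces: confusion matrix, classification rates with an
# explicit positive-class declaration, and regression agreement metrics.

#' Confusion matrix for binary predictions
#'
#' @param labels True binary values (0/1).
#' @param preds Predicted binary values (0/1); probabilities must be
#'   thresholded by the caller.
#' @param positive Which value counts as the positive class.
#' @return A `confusion_matrix`: list with counts `tp`, `tn`, `fp`, `fn`,
#'   the declared `positive` class and the 2x2 `table`.
#' @export
confusion_matrix <- function(labels, preds, positive = 1) {
  if (length(labels) != length(preds)) {
    stop("labels and preds must have equal length")
  }
  vals <- unique(c(labels, preds))
  if (!all(vals %in% c(0, 1))) stop("inputs must be binary 0/1")
  pos <- labels == positive
  posp <- preds == positive
  cm <- list(
    tp = sum(pos & posp), tn = sum(!pos & !posp),
    fp = sum(!pos & posp), fn = sum(pos & !posp),
    positive = positive
  )
  cm$table <- matrix(c(cm$tp, cm$fn, cm$fp, cm$tn), 2, 2,
                     dimnames = list(
                       predicted = c("positive", "negative"),
                       actual = c("positive", "negative")))
  class(cm) <- "confusion_matrix"
  cm
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> positive class = %s, n = %d\n",
              format(x$positive), x$tp + x$tn + x$fp + x$fn))
  print(x$table)
  invisible(x)
}

#' Accuracy, specificity and sensitivity
#'
#' `acc = (TP+TN)/n`, `sen = TP/(TP+FN)`, `spe = TN/(TN+FP)` under the
#' matrix's declared positive class. Because swapping the positive class
#' exchanges sensitivity and specificity, both conventions are reported
#' (`swapped` holds the rates with the other class as positive). Empty
#' denominators yield `NA`, not 0.
#'
#' @param cm A [confusion_matrix()].
#' @return List with `acc`, `sen`, `spe`, `positive` and `swapped`
#'   (`sen`/`spe` under the opposite convention).
#' @export
classification_metrics <- function(cm) {
  n <- cm$tp + cm$tn + cm$fp + cm$fn
  if (n == 0) stop("empty confusion matrix")
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  list(
    acc = (cm$tp + cm$tn) / n,
    sen = rate(cm$tp, cm$tp + cm$fn),
    spe = rate(cm$tn, cm$tn + cm$fp),
    positive = cm$positive,
    swapped = list(sen = rate(cm$tn, cm$tn + cm$fp),
                   spe = rate(cm$tp, cm$tp + cm$fn))
  )
}

#' Regression agreement metrics
#'
#' PLCC (Pearson), SROCC (Spearman with average ranks on ties) and RMSE
#' on the supplied scale.
#'
#' @param preds Predicted values.
#' @param targets Reference values.
#' @return List with `plcc`, `srocc`, `rmse`, `n`.
#' @export
regression_metrics <- function(preds, targets) {
  if (length(preds) != length(targets)) {
    stop("preds and targets must have equal length")
  }
  if (length(preds) < 2) stop("need at least 2 points")
  if (sd(preds) == 0 || sd(targets) == 0) {
    stop("constant input: correlations undefined")
  }
  list(
    plcc = cor(preds, targets),
    srocc = cor(preds, targets, method = "spearman"),
    rmse = sqrt(mean((preds - targets)^2)),
    n = length(preds)
  )
}

#' Full evaluation report
#'
#' @param labels,preds Binary classification arrays (optional).
#' @param reg_preds,reg_targets Regression arrays (optional), on the
#'   reporting (unnormalized SSQ) scale.
#' @param positive Positive class for the confusion matrix.
#' @return An `eval_report` list with `confusion`, `classification`,
#'   `regression` (whichever inputs were given).
#' @export
eval_report <- function(labels = NULL, preds = NULL, reg_preds = NULL,
                        reg_targets = NULL, positive = 1) {
  out <- list()
  if (!is.null(labels)) {
    cm <- confusion_matrix(labels, preds, positive)
    out$confusion <- cm
    out$classification <- classification_metrics(cm)
  }
  if (!is.null(reg_preds)) {
    out$regression <- regression_metrics(reg_preds, reg_targets)
  }
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  if (!is.null(x$classification)) {
    m <- x$classification
    cat(sprintf("classification: acc %.4f, sen %.4f, spe %.4f (positive = %s)\n",
                m$acc, m$sen, m$spe, format(m$positive)))
  }
  if (!is.null(x$regression)) {
    r <- x$regression
    cat(sprintf("regression: PLCC %.4f, SROCC %.4f, RMSE %.4f (n = %d)\n",
                r$plcc, r$srocc, r$rmse, r$n))
  }
  invisible(x)
}
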