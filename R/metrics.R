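# Binary-classification metric suite and threshold-sweep curves.

#' Confusion counts from predicted and true labels
#'
#' @param pred predicted 0/1 labels.
#' @param truth true 0/1 labels.
#' @return Named list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  list(tp = sum(pred == 1 & truth == 1), fp = sum(pred == 1 & truth == 0),
       tn = sum(pred == 0 & truth == 0), fn = sum(pred == 0 & truth == 1))
}

#' Threshold metrics from confusion counts
#'
#' Standard definitions: `Acc = (TP+TN)/total`, `Prec = TP/(TP+FP)`,
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `F1 = 2*Prec*Sn/(Prec+Sn)`, and
#' the Matthews correlation coefficient. Any zero denominator yields 0
#' for that metric and sets the `"flagged"` attribute. `literal = TRUE`
#' reproduces, for auditability, a nonstandard variant sometimes seen in
#' the site-recognition literature in which precision is computed as
#' `TP/(TP+FN)` (identical to sensitivity) and F1 omits the factor 2; it
#' is not used anywhere else in the package.
#'
#' @param tp,fp,tn,fn nonnegative confusion counts.
#' @param literal reproduce the nonstandard printed formulas.
#' @return Named numeric vector with `Acc`, `F1`, `Prec`, `Sn`, `Sp`,
#'   `MCC`.
#' @export
compute_metrics <- function(tp, fp, tn, fn, literal = FALSE) {
  if (is.list(tp)) { fp <- tp$fp; tn <- tp$tn; fn <- tp$fn; tp <- tp$tp }
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero")
  flagged <- FALSE
  safe <- function(num, den) {
    if (den == 0) { flagged <<- TRUE; 0 } else num / den
  }
  acc <- (tp + tn) / total
  sn <- safe(tp, tp + fn)
  sp <- safe(tn, tn + fp)
  prec <- if (literal) safe(tp, tp + fn) else safe(tp, tp + fp)
  f1 <- if (literal) safe(prec * sn, prec + sn) else safe(2 * prec * sn, prec + sn)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) { flagged <- TRUE; 0 } else {
    (tp * tn - fp * fn) / mcc_den
  }
  out <- c(Acc = acc, F1 = f1, Prec = prec, Sn = sn, Sp = sp, MCC = mcc)
  attr(out, "flagged") <- flagged
  out
}

#' ROC and precision-recall curves
#'
#' Threshold-sweep curves over the distinct score values (ties grouped).
#' AUC is the trapezoidal area under the ROC curve; AUPR is the step
#' (average-precision) area under the PR curve.
#'
#' @param scores finite numeric scores for the positive class.
#' @param labels binary 0/1 labels; both classes must be present.
#' @return List with data frames `roc` (fpr, tpr) and `pr`
#'   (recall, precision), and scalars `auc` and `aupr`.
#' @export
roc_pr <- function(scores, labels) {
  stopifnot(all(is.finite(scores)), length(scores) == length(labels))
  labels <- as.integer(labels)
  P <- sum(labels == 1); Ng <- sum(labels == 0)
  if (P == 0 || Ng == 0) stop("labels contain a single class")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  keep <- c(diff(s) != 0, TRUE)           # last index of each tie group
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  tpr <- c(0, tp / P); fpr <- c(0, fp / Ng)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  rec <- tp / P
  prec <- tp / (tp + fp)
  aupr <- sum(diff(c(0, rec)) * prec)
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = rec, precision = prec),
       auc = auc, aupr = aupr)
}

#' Write ROC/PR curves as TSV files
#'
#' @param cv result of [roc_pr()].
#' @param prefix path prefix; writes `<prefix>_roc.tsv` and
#'   `<prefix>_pr.tsv`.
#' @return The two paths, invisibly.
#' @export
write_curves <- function(cv, prefix) {
  p1 <- paste0(prefix, "_roc.tsv"); p2 <- paste0(prefix, "_pr.tsv")
  utils::write.table(cv$roc, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cv$pr, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
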