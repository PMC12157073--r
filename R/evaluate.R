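# Evaluation panel for imbalanced binary methylation-state prediction:
# ACC, ROC AUC, area under the precision-recall curve (average precision),
# F1, MCC, TNR, TPR, all at the strict > 0.5 decision rule.

#' Confusion counts at a threshold
#'
#' A site is called methylated iff its probability is strictly greater than
#' the threshold (0.5 by default, matching the prediction rounding rule).
#'
#' @param labels 0/1 vector of observed states.
#' @param probs Predicted probabilities, same length.
#' @param threshold Decision threshold.
#' @return Named integer vector tp, fp, tn, fn.
#' @export
confusion <- function(labels, probs, threshold = 0.5) {
  if (length(labels) != length(probs)) stop("labels and probs differ in length")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  pred <- as.integer(probs > threshold)
  c(tp = sum(pred == 1L & labels == 1L),
    fp = sum(pred == 1L & labels == 0L),
    tn = sum(pred == 0L & labels == 0L),
    fn = sum(pred == 0L & labels == 1L))
}

# Mann-Whitney form of the ROC AUC; ties between a positive and a negative
# score count one half
auc_score <- function(labels, probs) {
  pos <- probs[labels == 1L]
  neg <- probs[labels == 0L]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (as.numeric(length(pos)) * length(neg))
}

# Average precision: step-wise sum of precision at each recall increment,
# descending score order (ties grouped so the result is order-independent)
average_precision <- function(labels, probs) {
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || n_pos == length(labels)) return(NA_real_)
  o <- order(probs, decreasing = TRUE)
  y <- labels[o]; s <- probs[o]
  grp <- cumsum(!duplicated(s))
  tp_cum <- cumsum(y)
  n_cum <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)   # end of each tied block
  tp_b <- tp_cum[last]; n_b <- n_cum[last]
  prec <- tp_b / n_b
  d_tp <- diff(c(0, tp_b))
  sum(prec * d_tp) / n_pos
}

#' Full evaluation panel
#'
#' Computes ACC, ROC AUC, average precision (PRC), F1, MCC, TNR and TPR with
#' documented degenerate-case conventions: with single-class labels AUC and
#' PRC are NA with a warning while threshold metrics are still computed;
#' F1 is 0 when precision + recall is 0; MCC is 0 when any confusion-matrix
#' margin is 0.
#'
#' @param labels 0/1 vector of observed states.
#' @param probs Predicted probabilities.
#' @param threshold Decision threshold for the confusion-based metrics.
#' @return A `metrics_report` list: acc, auc, prc, f1, mcc, tnr, tpr, the
#'   confusion counts, n and the threshold.
#' @export
metrics <- function(labels, probs, threshold = 0.5) {
  cm <- confusion(labels, probs, threshold)
  tp <- cm[["tp"]]; fp <- cm[["fp"]]; tn <- cm[["tn"]]; fn <- cm[["fn"]]
  n <- length(labels)
  if (length(unique(labels)) < 2L) {
    warning("single-class labels: AUC and PRC are undefined")
  }
  prec <- if (tp + fp > 0L) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  denom <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (denom > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom else 0
  structure(list(
    acc = (tp + tn) / n,
    auc = auc_score(labels, probs),
    prc = average_precision(labels, probs),
    f1 = f1, mcc = mcc,
    tnr = if (tn + fp > 0L) tn / (tn + fp) else NA_real_,
    tpr = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn,
    n = n, threshold = threshold
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n=%d  ACC=%.4f  AUC=%s  PRC=%s  F1=%.4f  MCC=%.4f  TNR=%.4f  TPR=%.4f\n",
              x$n, x$acc,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)),
              ifelse(is.na(x$prc), "NA", sprintf("%.4f", x$prc)),
              x$f1, x$mcc, x$tnr, x$tpr))
  invisible(x)
}

#' Write a metrics report
#'
#' One-row TSV plus a JSON twin at `<path>.json`.
#'
#' @param report A `metrics_report`.
#' @param path Output TSV path.
#' @export
write_metrics <- function(report, path) {
  row <- data.table::as.data.table(unclass(report))
  data.table::fwrite(row, path, sep = "\t")
  jsonlite::write_json(unclass(report), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
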