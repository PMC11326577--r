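#' Binary confusion tables
#'
#' `confusion_table()` builds a table from explicit counts;
#' `binary_confusion()` counts calls against truth and records which
#' record ids fall in each cell, enabling the false-positive
#' reassessment adjustment.
#'
#' @param tp,fp,tn,fn non-negative counts
#' @return object of class `binary_confusion`
#' @export
confusion_table <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 fp_ids = NULL),
            class = "binary_confusion")
}

#' @rdname confusion_table
#' @param truth named logical truth vector
#' @param calls named logical predicted calls covering the same ids
#' @export
binary_confusion <- function(truth, calls) {
  missing <- setdiff(names(truth), names(calls))
  if (length(missing))
    stop("no prediction for record(s): ", paste(missing, collapse = ", "))
  calls <- calls[names(truth)]
  tab <- confusion_table(sum(truth & calls), sum(!truth & calls),
                         sum(!truth & !calls), sum(truth & !calls))
  tab$fp_ids <- names(truth)[!truth & calls]
  tab
}

#' @export
print.binary_confusion <- function(x, ...) {
  cat(sprintf("<binary_confusion> TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

# metric with zero-denominator flagging (0 + flag, never NaN)
.safe_ratio <- function(num, den, name, flags) {
  if (den == 0) {
    flags$zero <- c(flags$zero, name)
    list(value = 0, flags = flags)
  } else list(value = num / den, flags = flags)
}

#' Binary classification metrics
#'
#' Computes precision TP/(TP+FP), recall TP/(TP+FN), specificity
#' TN/(TN+FP), accuracy (TP+TN)/total, F1 as the harmonic mean
#' 2PR/(P+R), and the Matthews correlation coefficient
#' (TN·TP − FN·FP) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). Any metric
#' with a zero denominator is reported as 0 and listed in
#' `zero_denominator_flags`; an all-zero table is an error.
#'
#' @param table a [confusion_table()]
#' @param threshold decision threshold recorded in the report
#' @return object of class `metrics_report`
#' @export
binary_metrics <- function(table, threshold = 0.5) {
  stopifnot(inherits(table, "binary_confusion"))
  tp <- table$tp; fp <- table$fp; tn <- table$tn; fn <- table$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("all-zero confusion table")
  flags <- list(zero = character(0))
  p <- .safe_ratio(tp, tp + fp, "precision", flags)
  r <- .safe_ratio(tp, tp + fn, "recall", p$flags)
  s <- .safe_ratio(tn, tn + fp, "specificity", r$flags)
  flags <- s$flags
  precision <- p$value; recall <- r$value
  accuracy <- (tp + tn) / total
  if (precision + recall == 0) {
    flags$zero <- c(flags$zero, "f1")
    f1 <- 0
  } else f1 <- 2 * precision * recall / (precision + recall)
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 == 0) {
    flags$zero <- c(flags$zero, "mcc")
    mcc <- 0
  } else mcc <- (tn * tp - fn * fp) / sqrt(den2)
  structure(list(precision = precision, recall = recall,
                 specificity = s$value, accuracy = accuracy, f1 = f1,
                 mcc = mcc, pr_auc = NA_real_, counts = table,
                 threshold = threshold,
                 zero_denominator_flags = flags$zero),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> P=%.4f R=%.4f Sp=%.4f Acc=%.4f F1=%.4f MCC=%.4f%s\n",
    x$precision, x$recall, x$specificity, x$accuracy, x$f1, x$mcc,
    if (is.na(x$pr_auc)) "" else sprintf(" PR-AUC=%.4f", x$pr_auc)))
  if (length(x$zero_denominator_flags))
    cat("  zero-denominator:", paste(x$zero_denominator_flags,
                                     collapse = ", "), "\n")
  invisible(x)
}

#' Token confusion matrix
#'
#' Pools residues over all records: entry (i, j) counts residues with
#' true label i predicted as j, label order fixed to
#' [fold_labels()]. A truth/prediction length mismatch is an error
#' naming the record.
#'
#' @param truth_labels,pred_labels equal-length lists of per-residue
#'   label vectors (optionally named by record id)
#' @return 4 x 4 count matrix of class `token_confusion`
#' @export
token_confusion <- function(truth_labels, pred_labels) {
  if (length(truth_labels) == 0L) stop("no records to tabulate")
  if (length(truth_labels) != length(pred_labels))
    stop("truth and prediction lists differ in length")
  M <- matrix(0L, 4L, 4L, dimnames = list(truth = .TRAINABLE_LABELS,
                                          predicted = .TRAINABLE_LABELS))
  nm <- names(truth_labels)
  for (i in seq_along(truth_labels)) {
    t <- truth_labels[[i]]; p <- pred_labels[[i]]
    if (length(t) != length(p))
      stop("label length mismatch for record '",
           if (!is.null(nm) && nzchar(nm[i])) nm[i] else i, "'")
    M <- M + table(factor(t, .TRAINABLE_LABELS),
                   factor(p, .TRAINABLE_LABELS))
  }
  structure(unclass(as.matrix(M)), class = c("token_confusion", "matrix"))
}

#' Micro-averaged token metrics
#'
#' Pools all residues before computing metrics, which makes micro
#' precision, recall, F1 and accuracy all equal trace/total — the
#' signature of micro-averaging. The multi-class Matthews correlation
#' uses the generalised R_k statistic.
#'
#' @param table a K x K count matrix (rows = truth)
#' @return a `metrics_report` (pr_auc not applicable)
#' @export
micro_token_metrics <- function(table) {
  M <- unclass(as.matrix(table))
  storage.mode(M) <- "double"  # counts can overflow integer products
  s <- sum(M)
  if (s == 0) stop("empty confusion matrix")
  c0 <- sum(diag(M))
  acc <- c0 / s
  tvec <- rowSums(M)  # true-label totals
  pvec <- colSums(M)  # predicted totals
  num <- c0 * s - sum(pvec * tvec)
  den <- sqrt(s^2 - sum(pvec^2)) * sqrt(s^2 - sum(tvec^2))
  flags <- character(0)
  if (den == 0) {
    mcc <- 0; flags <- "mcc"
  } else mcc <- num / den
  structure(list(precision = acc, recall = acc, specificity = NA_real_,
                 accuracy = acc, f1 = acc, mcc = mcc,
                 pr_auc = NA_real_, counts = M, threshold = NA_real_,
                 zero_denominator_flags = flags),
            class = "metrics_report")
}

#' Precision-recall AUC (average precision)
#'
#' Step-wise average precision: thresholds sweep the distinct scores
#' from high to low (tied scores form a single threshold step) and
#' the area is the sum of precision times the recall increment at
#' each step. Invariant under strictly monotone transforms of the
#' scores. Requires both classes in the truth.
#'
#' @param scores numeric scores, higher = more positive
#' @param truth logical (or 0/1) true classes, same length
#' @return average precision in \[0, 1\]
#' @export
pr_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth))
    stop("scores and truth differ in length")
  npos <- sum(truth)
  if (npos == 0L || npos == length(truth))
    stop("PR AUC needs at least one positive and one negative")
  thr <- sort(unique(scores), decreasing = TRUE)
  auc <- 0; prev_recall <- 0
  for (t in thr) {
    called <- scores >= t
    prec <- sum(truth & called) / sum(called)
    rec <- sum(truth & called) / npos
    auc <- auc + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  auc
}

#' Multi-tool benchmark report
#'
#' One metrics row per tool, computed on the identical record set: a
#' tool missing any truth record is an error listing the ids, never a
#' silent exclusion. Calls are score >= threshold (ties positive);
#' PR-AUC is computed from the scores.
#'
#' @param tool_scores named list: per tool, a named numeric score
#'   vector keyed by record id
#' @param truth named logical truth vector
#' @param threshold decision threshold
#' @return data frame with one row per tool and columns tool,
#'   tp/fp/tn/fn, precision, recall, specificity, accuracy, f1, mcc,
#'   pr_auc; full `metrics_report`s in attribute `"reports"`
#' @export
benchmark_report <- function(tool_scores, truth, threshold = 0.5) {
  stopifnot(is.list(tool_scores), length(tool_scores) >= 1)
  reports <- list()
  rows <- list()
  for (tool in names(tool_scores)) {
    sc <- tool_scores[[tool]]
    missing <- setdiff(names(truth), names(sc))
    if (length(missing))
      stop("tool '", tool, "' is missing prediction(s) for: ",
           paste(missing, collapse = ", "))
    sc <- sc[names(truth)]
    tab <- binary_confusion(truth, sc >= threshold)
    rep <- binary_metrics(tab, threshold)
    rep$pr_auc <- pr_auc(sc, truth)
    reports[[tool]] <- rep
    rows[[tool]] <- data.frame(
      tool = tool, tp = tab$tp, fp = tab$fp, tn = tab$tn, fn = tab$fn,
      precision = rep$precision, recall = rep$recall,
      specificity = rep$specificity, accuracy = rep$accuracy,
      f1 = rep$f1, mcc = rep$mcc, pr_auc = rep$pr_auc,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' False-positive reassessment adjustment
#'
#' Re-evaluation of flagged false positives can reveal genuine
#' positives missed by the reference truth; records confirmed not to
#' be real positives stay FPs, while the re-assessed ones are moved
#' to true negatives and the metrics recomputed (TP and FN are
#' untouched). `reclassify` is either a count or a vector of record
#' ids; ids must currently be FPs of the table.
#'
#' @param table a [confusion_table()] / [binary_confusion()]
#' @param reclassify integer count of FPs to move to TN, or character
#'   ids (requires a table built by [binary_confusion()])
#' @param threshold recorded decision threshold
#' @return a `metrics_report` on the adjusted table
#' @export
adjust_false_positives <- function(table, reclassify, threshold = 0.5) {
  stopifnot(inherits(table, "binary_confusion"))
  if (is.character(reclassify)) {
    if (is.null(table$fp_ids))
      stop("this table does not track FP ids; pass a count instead")
    bad <- setdiff(reclassify, table$fp_ids)
    if (length(bad))
      stop("id(s) not currently false positives: ",
           paste(bad, collapse = ", "))
    n <- length(unique(reclassify))
  } else {
    n <- as.integer(reclassify)
    if (n < 0 || n > table$fp)
      stop("cannot reclassify ", n, " of ", table$fp, " false positives")
  }
  adj <- confusion_table(table$tp, table$fp - n, table$tn + n, table$fn)
  if (!is.null(table$fp_ids) && is.character(reclassify))
    adj$fp_ids <- setdiff(table$fp_ids, reclassify)
  binary_metrics(adj, threshold)
}
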