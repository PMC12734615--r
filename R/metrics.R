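# Confusion-matrix evaluation: per-class one-vs-rest tallies, the binary
# metric suite (accuracy, precision, recall, F1, MCC), macro/micro global
# metrics with the covariance-form multiclass MCC, and one-vs-rest ROC and
# precision-recall curves with trapezoidal AUC.

#' Confusion matrix from labels
#'
#' Counts with rows = true class, columns = predicted class, in the order
#' of `classes`.
#'
#' @param truth,pred Vectors of class labels (character or factor) or
#'   1-based integer indices.
#' @param classes Class label order (default [bilight_classes()]).
#' @return A C x C integer matrix with dimnames.
#' @export
confusion_matrix <- function(truth, pred, classes = bilight_classes()) {
  to_idx <- function(x) if (is.numeric(x)) as.integer(x) else match(as.character(x), classes)
  ti <- to_idx(truth); pi <- to_idx(pred)
  stopifnot(!anyNA(ti), !anyNA(pi))
  C <- length(classes)
  cm <- matrix(0L, C, C, dimnames = list(truth = classes, predicted = classes))
  for (i in seq_along(ti)) cm[ti[i], pi[i]] <- cm[ti[i], pi[i]] + 1L
  cm
}

#' One-vs-rest reduction of a confusion matrix
#'
#' Reduces the multiclass counts to the binary tally for one class:
#' TP = diagonal cell, FN = rest of the row, FP = rest of the column,
#' TN = remainder.
#'
#' @param cm C x C confusion matrix (rows = truth).
#' @param class Class index (1-based) or label matching the dimnames.
#' @return Named list with `TP`, `TN`, `FP`, `FN`.
#' @export
one_vs_rest <- function(cm, class) {
  c <- if (is.numeric(class)) as.integer(class) else match(class, rownames(cm))
  stopifnot(!is.na(c), c >= 1, c <= nrow(cm))
  tp <- cm[c, c]
  fn <- sum(cm[c, ]) - tp
  fp <- sum(cm[, c]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Binary classification metrics from a tally
#'
#' Formula-exact accuracy, precision, recall, F1 and Matthews correlation
#' from TP/TN/FP/FN counts. Undefined 0/0 ratios are reported as 0 and
#' flagged via the `degenerate` field; MCC is 0 when any marginal is zero.
#'
#' @param tally List with `TP`, `TN`, `FP`, `FN` (see [one_vs_rest()]).
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`, `mcc`,
#'   `degenerate`.
#' @export
binary_metrics <- function(tally) {
  tp <- tally$TP; tn <- tally$TN; fp <- tally$FP; fn <- tally$FN
  n <- tp + tn + fp + fn
  if (n == 0) stop("empty tally", call. = FALSE)
  degenerate <- (tp + fp) == 0 || (tp + fn) == 0
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom2)
  list(accuracy = (tp + tn) / n, precision = precision, recall = recall,
       f1 = f1, mcc = mcc, degenerate = degenerate)
}

#' Global metrics from a confusion matrix
#'
#' Overall accuracy, macro-averaged (unweighted class means) and
#' micro-averaged precision/recall/F1, and the multiclass Matthews
#' correlation in its covariance (C x C) generalization, which reduces to
#' the binary formula at C = 2.
#'
#' @param cm C x C confusion matrix (rows = truth).
#' @return Named list: `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, `micro_precision`, `micro_recall`, `micro_f1`,
#'   `multiclass_mcc`.
#' @export
global_metrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), sum(cm) > 0)
  C <- nrow(cm)
  per <- lapply(seq_len(C), function(c) binary_metrics(one_vs_rest(cm, c)))
  s <- sum(cm); tr <- sum(diag(cm))
  pk <- colSums(cm); tk <- rowSums(cm)
  denom <- sqrt(s^2 - sum(as.numeric(pk)^2)) * sqrt(s^2 - sum(as.numeric(tk)^2))
  mcc <- if (denom == 0) 0 else (tr * s - sum(as.numeric(pk) * tk)) / denom
  # micro: pooled one-vs-rest counts (equal to accuracy on single-label data)
  tp <- tr; fp <- s - tr; fn <- s - tr
  micro_p <- safe_div(tp, tp + fp); micro_r <- safe_div(tp, tp + fn)
  list(accuracy = tr / s,
       macro_precision = mean(vapply(per, `[[`, numeric(1), "precision")),
       macro_recall = mean(vapply(per, `[[`, numeric(1), "recall")),
       macro_f1 = mean(vapply(per, `[[`, numeric(1), "f1")),
       micro_precision = micro_p, micro_recall = micro_r,
       micro_f1 = safe_div(2 * micro_p * micro_r, micro_p + micro_r),
       multiclass_mcc = mcc)
}

# trapezoidal area under a curve given x (not necessarily sorted) and y
trapezoid_auc <- function(x, y) {
  o <- order(x)
  sum(diff(x[o]) * (utils::head(y[o], -1) + utils::tail(y[o], -1)) / 2)
}

#' One-vs-rest ROC and precision-recall curves
#'
#' For each class, thresholds sweep the unique predicted scores (ties move
#' together); ROC AUC and PR AUC are trapezoidal. A class without positives
#' or without negatives is skipped and flagged.
#'
#' @param scores (N, C) matrix of class scores or probabilities.
#' @param labels Length-N vector of true classes (labels or 1-based
#'   indices).
#' @param classes Class order matching the columns of `scores`.
#' @return A list per class: `roc` (data frame fpr/tpr), `pr` (data frame
#'   recall/precision), `roc_auc`, `pr_auc`, `skipped`.
#' @export
roc_pr_curves <- function(scores, labels, classes = bilight_classes()) {
  li <- if (is.numeric(labels)) as.integer(labels) else match(as.character(labels), classes)
  out <- list()
  for (c in seq_len(ncol(scores))) {
    pos <- li == c
    if (!any(pos) || all(pos)) {
      out[[classes[c]]] <- list(skipped = TRUE)
      next
    }
    sc <- scores[, c]
    thr <- sort(unique(sc), decreasing = TRUE)
    np <- sum(pos); nn <- sum(!pos)
    tpr <- fpr <- prec <- numeric(length(thr))
    for (i in seq_along(thr)) {
      call_pos <- sc >= thr[i]
      tp <- sum(call_pos & pos); fp <- sum(call_pos & !pos)
      tpr[i] <- tp / np; fpr[i] <- fp / nn
      prec[i] <- safe_div(tp, tp + fp)
    }
    roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
    pr <- data.frame(recall = c(0, tpr), precision = c(1, prec))
    out[[classes[c]]] <- list(
      roc = roc, pr = pr,
      roc_auc = trapezoid_auc(roc$fpr, roc$tpr),
      pr_auc = trapezoid_auc(pr$recall, pr$precision),
      skipped = FALSE)
  }
  out
}

#' Per-class and global evaluation report
#'
#' Builds the full metric report from predictions: confusion matrix,
#' one-vs-rest metrics per class, global metrics, and (when scores are
#' given) ROC/PR AUCs.
#'
#' @param truth True labels.
#' @param pred Predicted labels.
#' @param scores Optional (N, C) score matrix for the curves.
#' @param classes Class order.
#' @return Object of class `bilight_report`.
#' @export
metric_report <- function(truth, pred, scores = NULL,
                          classes = bilight_classes()) {
  cm <- confusion_matrix(truth, pred, classes)
  per_class <- do.call(rbind, lapply(seq_along(classes), function(c) {
    m <- binary_metrics(one_vs_rest(cm, c))
    data.frame(class = classes[c], precision = m$precision,
               recall = m$recall, f1 = m$f1, accuracy = m$accuracy,
               mcc = m$mcc, stringsAsFactors = FALSE)
  }))
  glob <- global_metrics(cm)
  curves <- if (!is.null(scores)) roc_pr_curves(scores, truth, classes)
  structure(list(confusion = cm, per_class = per_class, global = glob,
                 curves = curves, n = sum(cm)),
            class = "bilight_report")
}

#' @export
print.bilight_report <- function(x, digits = 4, ...) {
  cat(sprintf("Evaluation report (%d tiles)\n", x$n))
  pc <- x$per_class
  pc[, -1] <- round(pc[, -1], digits)
  print(pc, row.names = FALSE)
  g <- x$global
  cat(sprintf("global: accuracy %.4f | macro P/R/F1 %.4f/%.4f/%.4f | MCC %.4f\n",
              g$accuracy, g$macro_precision, g$macro_recall, g$macro_f1,
              g$multiclass_mcc))
  if (!is.null(x$curves)) {
    auc <- vapply(x$curves, function(k)
      if (isTRUE(k$skipped)) NA_real_ else k$roc_auc, numeric(1))
    cat("ROC AUC:", paste(sprintf("%s %.4f", names(auc), auc), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write a report to disk
#'
#' Emits the confusion matrix and per-class table as CSV, the global
#' metrics (plus per-class AUCs) as JSON, and the ROC/PR curves as CSV
#' point lists.
#'
#' @param report A `bilight_report`.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$confusion, file.path(dir, "confusion.csv"))
  utils::write.csv(report$per_class, file.path(dir, "per_class.csv"),
                   row.names = FALSE)
  glob <- report$global
  if (!is.null(report$curves)) {
    glob$roc_auc <- lapply(report$curves, function(k)
      if (isTRUE(k$skipped)) NA else k$roc_auc)
    glob$pr_auc <- lapply(report$curves, function(k)
      if (isTRUE(k$skipped)) NA else k$pr_auc)
    pts <- do.call(rbind, lapply(names(report$curves), function(cl) {
      k <- report$curves[[cl]]
      if (isTRUE(k$skipped)) return(NULL)
      rbind(data.frame(class = cl, curve = "roc", x = k$roc$fpr, y = k$roc$tpr),
            data.frame(class = cl, curve = "pr", x = k$pr$recall,
                       y = k$pr$precision))
    }))
    utils::write.csv(pts, file.path(dir, "curves.csv"), row.names = FALSE)
  }
  jsonlite::write_json(glob, file.path(dir, "global.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
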