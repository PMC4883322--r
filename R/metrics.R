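# Detection and classification performance metrics. Rates are kept at full
# precision internally; print methods display one decimal, rounded half-up.

#' Round half-up
#'
#' Standard `round()` rounds half to even; performance tables in this field
#' conventionally round half away from zero (e.g. 90.05 displays as 90.1).
#' A tiny epsilon absorbs binary representation error at the midpoint.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Detection metrics from confusion counts
#'
#' The aggression detection rate is the recall of the aggressive class,
#' `ADR = TP / (TP + FN) * 100`; the false positive rate is
#' `FPR = FP / (FP + TN) * 100`; the false negative rate is
#' `FNR = FN / (TP + FN) * 100`. ADR and FNR are complementary:
#' they sum to 100 for any counts.
#'
#' @param TP,FP,TN,FN Non-negative confusion counts; `TP + FN` and
#'   `FP + TN` must be positive.
#' @return A `detection_metrics` object with the counts and the three rates
#'   in percent (full precision).
#' @export
detection_metrics <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0)) stop("confusion counts must be >= 0", call. = FALSE)
  if (TP + FN == 0)
    stop("TP + FN = 0: detection rates undefined", call. = FALSE)
  if (FP + TN == 0)
    stop("FP + TN = 0: false positive rate undefined", call. = FALSE)
  structure(
    list(TP = TP, FP = FP, TN = TN, FN = FN,
         ADR = TP / (TP + FN) * 100,
         FPR = FP / (FP + TN) * 100,
         FNR = FN / (TP + FN) * 100),
    class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat("Aggression detection (out-of-fold pooled counts)\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  ADR %.1f%%  FPR %.1f%%  FNR %.1f%%\n",
              round_half_up(x$ADR), round_half_up(x$FPR),
              round_half_up(x$FNR)))
  invisible(x)
}

#' Classification metrics from a 2x2 confusion matrix
#'
#' Treating each class as positive in turn: precision is
#' `TP / (TP + FP) * 100` (column-wise) and recall is `TP / (TP + FN) * 100`
#' (row-wise), with truth in rows and predictions in columns. The macro
#' averages are the unweighted means of the two per-class values. A class
#' never predicted has undefined precision, reported as 0 with a warning.
#'
#' @param confusion 2x2 table/matrix, rows = truth, columns = predicted,
#'   identically ordered.
#' @return A `class_metrics` object with per-class `precision` and `recall`
#'   (named vectors, percent) and `macro_precision`, `macro_recall`.
#' @export
classification_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == 2, ncol(confusion) == 2)
  if (any(rowSums(confusion) == 0))
    stop("each true class must have at least one member", call. = FALSE)
  classes <- rownames(confusion)
  if (is.null(classes)) classes <- c("class1", "class2")
  prec <- diag(confusion) / colSums(confusion) * 100
  if (any(colSums(confusion) == 0)) {
    warning("a class has no predicted positives; its precision reported as 0")
    prec[colSums(confusion) == 0] <- 0
  }
  rec <- diag(confusion) / rowSums(confusion) * 100
  names(prec) <- names(rec) <- classes
  structure(
    list(precision = prec, recall = rec,
         macro_precision = mean(prec), macro_recall = mean(rec)),
    class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat("Aggression classification (out-of-fold pooled counts)\n")
  for (cl in names(x$precision))
    cat(sprintf("  %-24s precision %.1f%%  recall %.1f%%\n", cl,
                round_half_up(x$precision[cl]), round_half_up(x$recall[cl])))
  cat(sprintf("  %-24s precision %.1f%%  recall %.1f%%\n", "macro average",
              round_half_up(x$macro_precision),
              round_half_up(x$macro_recall)))
  invisible(x)
}
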