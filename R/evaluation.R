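#' Confusion matrix and performance metrics for variant-level calls
#'
#' Tabulates truth against prediction over S/R labels with resistant (R) as
#' the positive class, then derives accuracy, specificity, Matthews
#' correlation coefficient and per-class precision/recall/F1. The per-class
#' block is computed twice, once treating R as positive and once treating S
#' as positive, so both orientations of the report are available.
#'
#' MCC denominators with a zero factor are substituted with 0 and flagged
#' via \code{mcc_degenerate}.
#'
#' @param truth character vector of known labels, each "S" or "R".
#' @param predicted character vector of predicted labels, same length.
#' @return object of class \code{MetricsReport}: list with
#'   \code{confusion} (named counts TP/FP/TN/FN, R positive),
#'   \code{accuracy}, \code{specificity}, \code{mcc},
#'   \code{mcc_degenerate}, and \code{per_class} (data.frame with rows
#'   "S" and "R": precision, recall, f1).
#' @export
#' @examples
#' calls <- reference_variant_calls("dabrafenib")
#' confusion_and_metrics(calls$status, calls$predicted)
confusion_and_metrics <- function(truth, predicted) {
  if (length(truth) == 0L || length(truth) != length(predicted)) {
    stop("confusion_and_metrics(): truth and predicted must be equal-length and nonempty")
  }
  truth <- toupper(truth)
  predicted <- toupper(predicted)
  bad <- setdiff(unique(c(truth, predicted)), c("S", "R"))
  if (length(bad) > 0) {
    stop(sprintf("confusion_and_metrics(): labels outside {S, R}: %s",
                 paste(bad, collapse = ", ")))
  }
  tp <- sum(truth == "R" & predicted == "R")
  fp <- sum(truth == "S" & predicted == "R")
  tn <- sum(truth == "S" & predicted == "S")
  fn <- sum(truth == "R" & predicted == "S")
  n <- tp + fp + tn + fn
  accuracy <- (tp + tn) / n
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc_degenerate <- denom2 == 0
  mcc <- if (mcc_degenerate) 0 else
    (tp * tn - fp * fn) / sqrt(denom2)
  class_block <- function(pos) {
    ptp <- sum(truth == pos & predicted == pos)
    pfp <- sum(truth != pos & predicted == pos)
    pfn <- sum(truth == pos & predicted != pos)
    precision <- if (ptp + pfp > 0) ptp / (ptp + pfp) else NA_real_
    recall <- if (ptp + pfn > 0) ptp / (ptp + pfn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    c(precision = precision, recall = recall, f1 = f1)
  }
  per_class <- rbind(S = class_block("S"), R = class_block("R"))
  structure(
    list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
         accuracy = accuracy, specificity = specificity, mcc = mcc,
         mcc_degenerate = mcc_degenerate,
         per_class = as.data.frame(per_class)),
    class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cm <- x$confusion
  cat("MetricsReport (R = positive class)\n")
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              cm["TP"], cm["FP"], cm["TN"], cm["FN"]))
  cat(sprintf("  accuracy %.4f | specificity %.4f | MCC %.4f%s\n",
              x$accuracy, x$specificity, x$mcc,
              if (x$mcc_degenerate) " (degenerate denominator)" else ""))
  for (cl in rownames(x$per_class)) {
    cat(sprintf("  class %s: precision %.4f recall %.4f F1 %.4f\n", cl,
                x$per_class[cl, "precision"], x$per_class[cl, "recall"],
                x$per_class[cl, "f1"]))
  }
  invisible(x)
}

#' Write a MetricsReport as a metrics-table TSV
#'
#' Rows: accuracy, specificity, MCC, then per-class recall/precision/F1 —
#' the layout of the published performance-metrics table.
#'
#' @param x a \code{MetricsReport} (or named list of them, one column per
#'   model).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_metrics_tsv <- function(x, path) {
  if (inherits(x, "MetricsReport")) x <- list(model = x)
  col <- function(m) {
    c(Accuracy = m$accuracy, Specificity = m$specificity, MCC = m$mcc,
      `Sensitive Recall` = m$per_class["S", "recall"],
      `Sensitive Precision` = m$per_class["S", "precision"],
      `Sensitive F1` = m$per_class["S", "f1"],
      `Resistant Recall` = m$per_class["R", "recall"],
      `Resistant Precision` = m$per_class["R", "precision"],
      `Resistant F1` = m$per_class["R", "f1"])
  }
  tab <- do.call(cbind, lapply(x, col))
  df <- data.frame(Metric = rownames(tab), round(tab, 4),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
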