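#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v)))
    stop_validation("counts must be non-negative integers")
  if (sum(v) == 0) stop_validation("all-zero confusion counts")
  structure(as.list(v), class = "confusion_counts")
}

#' The six performance measures from confusion counts
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(FP+TN),
#' precision = TP/(TP+FP), accuracy = (TP+TN)/(TP+TN+FP+FN),
#' F-measure = 2TP/(2TP+FP+FN). A metric whose denominator is zero is
#' reported as 0 and listed in the `undefined` attribute (with a warning)
#' rather than dropped, so averages over many tasks stay auditable. AUC is
#' not derivable from counts alone; pass it via `auc` (e.g. from
#' [roc_auc()]), otherwise it is reported as `NA`.
#'
#' @param c a [confusion_counts()].
#' @param auc optional AUC to carry into the row.
#' @return Named numeric vector of the six metrics.
#' @export
metrics_from_counts <- function(c, auc = NA_real_) {
  stopifnot(inherits(c, "confusion_counts"))
  safe <- function(num, den, name) {
    if (den == 0) { und <<- c(und, name); 0 } else num / den
  }
  und <- character()
  out <- c(
    sensitivity = safe(c$tp, c$tp + c$fn, "sensitivity"),
    specificity = safe(c$tn, c$fp + c$tn, "specificity"),
    precision   = safe(c$tp, c$tp + c$fp, "precision"),
    accuracy    = (c$tp + c$tn) / (c$tp + c$tn + c$fp + c$fn),
    f_measure   = safe(2 * c$tp, 2 * c$tp + c$fp + c$fn, "f_measure"),
    auc         = auc)
  if (length(und)) {
    warning("undefined metrics (zero denominator) reported as 0: ",
            paste(und, collapse = ", "))
    attr(out, "undefined") <- und
  }
  out
}

#' ROC curve and area under the curve
#'
#' Thresholds are swept over every distinct score; ties share a rank, so
#' the AUC equals the Mann-Whitney pair-counting statistic
#' (ties counted 1/2) and the curve is integrated with the trapezoidal rule.
#'
#' @param scores numeric classifier scores, larger = more positive.
#' @param labels binary labels (0/1 or logical), both classes present.
#' @return List with `auc` and `roc` (data.frame `fpr`, `tpr` from (0,0) to
#'   (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels != 0)
  if (length(scores) != length(labels)) stop_validation("length mismatch")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop_validation("both classes must be present for ROC analysis")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores so each distinct score is one operating point
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1L - y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / np); fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}

#' Per-pair metrics table with an average row
#'
#' Collects one metrics row per one-vs-one class pair and appends the
#' column-wise arithmetic mean, mirroring the layout used for pairwise
#' classifier comparisons.
#'
#' @param rows named list of metric rows (as from [metrics_from_counts()]),
#'   names like `"3-4"`, or a data.frame with columns `class_a`, `class_b`
#'   and the metrics.
#' @return A data.frame with columns `class_a`, `class_b`, the six metrics,
#'   and a final `Average` row.
#' @export
pair_table <- function(rows) {
  if (is.data.frame(rows)) {
    df <- rows
  } else {
    if (!length(rows)) stop_validation("no metric rows")
    ab <- do.call(rbind, strsplit(names(rows), "-", fixed = TRUE))
    df <- cbind(data.frame(class_a = as.integer(ab[, 1]),
                           class_b = as.integer(ab[, 2])),
                as.data.frame(do.call(rbind, rows)))
  }
  metric_cols <- setdiff(names(df), c("class_a", "class_b"))
  avg <- df[1, , drop = FALSE]
  avg$class_a <- NA_integer_; avg$class_b <- NA_integer_
  for (mc in metric_cols) avg[[mc]] <- mean(df[[mc]])
  out <- rbind(df, avg)
  rownames(out) <- c(paste0(df$class_a, "-", df$class_b), "Average")
  out
}
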