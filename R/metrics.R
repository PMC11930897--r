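# Confusion-matrix metric panel. All metrics are computed on the exact
# integer cells; percentages are formatted only at print time (one decimal,
# round half up). Conventions for degenerate denominators: MCC -> 0 when any
# marginal is empty; recall/precision/F undefined (NA, flagged) when their
# denominator is empty.

#' Build a confusion matrix from binary predictions and labels
#'
#' "Positive" means model-predicted invasive; "true" means pathology-
#' confirmed invasive. TP: predicted invasive, confirmed invasive; FP:
#' predicted invasive, confirmed noninvasive; FN: predicted noninvasive,
#' confirmed invasive; TN: predicted noninvasive, confirmed noninvasive.
#'
#' @param predictions logical vector (TRUE = model-positive).
#' @param labels logical vector (TRUE = invasive by pathology).
#' @return object of class `confusion_matrix`: list with integer `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
#' @examples
#' confusion_matrix(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
confusion_matrix <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must have equal length")
  }
  if (length(predictions) == 0) stop("empty predictions")
  predictions <- as.logical(predictions)
  labels <- as.logical(labels)
  if (anyNA(predictions) || anyNA(labels)) {
    stop("predictions and labels must not contain NA")
  }
  new_confusion_matrix(tp = sum(predictions & labels),
                       fp = sum(predictions & !labels),
                       fn = sum(!predictions & labels),
                       tn = sum(!predictions & !labels))
}

#' Construct a confusion matrix from its four cells
#'
#' @param tp,fp,fn,tn nonnegative integer cell counts.
#' @return object of class `confusion_matrix`.
#' @export
new_confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop("confusion-matrix cells must be nonnegative integers")
  }
  cells <- as.integer(round(cells))
  structure(list(tp = cells[1], fp = cells[2], fn = cells[3], tn = cells[4]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              pathology = c("invasive", "noninvasive")))
  print(m)
  invisible(x)
}

#' Diagnostic metric panel from a confusion matrix
#'
#' Computes recall (sensitivity), precision (PPV), accuracy, F1, the
#' weighted F-beta score `(1 + beta^2) P R / (beta^2 P + R)`, and the
#' Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. `beta < 1`
#' weights precision over recall; the default `beta = 0.5` attenuates the
#' influence of false negatives. A zero MCC denominator yields 0 by
#' convention; an empty recall or precision denominator yields NA with the
#' affected metric named in the `undefined` attribute.
#'
#' @param cm a `confusion_matrix`.
#' @param beta positive weight for the F-beta score.
#' @return object of class `metric_panel`: list with `recall`, `precision`,
#'   `accuracy`, `f1`, `f_weighted`, `mcc`, `beta`, and the cells.
#' @export
#' @examples
#' panel_from_cm(new_confusion_matrix(131, 14, 7, 17))
panel_from_cm <- function(cm, beta = 0.5) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta <= 0) {
    stop("beta must be a single positive number")
  }
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("confusion matrix is empty")
  undefined <- character(0)

  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "recall"); NA_real_
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "precision"); NA_real_
  }
  accuracy <- (tp + tn) / total
  fbeta <- function(b) {
    if (is.na(precision) || is.na(recall)) return(NA_real_)
    den <- b^2 * precision + recall
    if (den == 0) return(NA_real_)
    (1 + b^2) * precision * recall / den
  }
  f1 <- fbeta(1)
  f_weighted <- fbeta(beta)
  if (is.na(f1)) undefined <- union(undefined, "f1")
  if (is.na(f_weighted)) undefined <- union(undefined, "f_weighted")

  # products as doubles to avoid integer overflow on large cohorts
  den2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den2 > 0) {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den2)
  } else 0

  structure(list(recall = recall, precision = precision, accuracy = accuracy,
                 f1 = f1, f_weighted = f_weighted, mcc = mcc, beta = beta,
                 cm = cm),
            undefined = undefined, class = "metric_panel")
}

#' Round half up to one decimal on the percent scale
#'
#' Display helper matching the convention of clinical accuracy tables:
#' fractions are multiplied by 100 and rounded half-up to one decimal.
#' Internal computations always use the exact fractions.
#'
#' @param x fraction(s) in `[-1, 1]`.
#' @param digits decimals to keep (default 1).
#' @return numeric percent value(s).
#' @export
#' @examples
#' percent(131 / 138)  # 94.9
percent <- function(x, digits = 1) {
  s <- sign(x)
  s * floor(abs(x) * 100 * 10^digits + 0.5) / 10^digits
}

#' @export
print.metric_panel <- function(x, ...) {
  cm <- x$cm
  cat(sprintf("Confusion cells: TP=%d FP=%d FN=%d TN=%d (n=%d)\n",
              cm$tp, cm$fp, cm$fn, cm$tn, cm$tp + cm$fp + cm$fn + cm$tn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", percent(v))
  cat("  Recall:    ", fmt(x$recall), "\n")
  cat("  Precision: ", fmt(x$precision), "\n")
  cat("  MCC:       ", fmt(x$mcc), "\n")
  cat("  F1:        ", fmt(x$f1), "\n")
  cat(sprintf("  F_beta (beta=%g): %s\n", x$beta, fmt(x$f_weighted)))
  cat("  Accuracy:  ", fmt(x$accuracy), "\n")
  invisible(x)
}
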