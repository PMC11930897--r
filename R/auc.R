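# Ordinal ROC AUC as the tie-corrected Mann-Whitney probability, with
# variance from DeLong structural components (placement values). Midranks
# give the same estimate as averaging the 0/0.5/1 kernel over all
# positive x negative pairs, in O(n log n).

delong_components <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must not be NA")
  m <- sum(labels)
  n <- sum(!labels)
  if (m == 0 || n == 0) {
    stop("ROC undefined: labels must contain both a positive and a negative")
  }
  x <- scores[labels]
  y <- scores[!labels]
  r_all <- rank(c(x, y), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y, ties.method = "average")) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' Ordinal ROC AUC with DeLong variance
#'
#' The AUC is the probability that a randomly chosen invasive nodule
#' receives a strictly higher ordinal score than a randomly chosen
#' noninvasive one, counting ties as 1/2 (tie-corrected Mann-Whitney).
#' Scores are typically the category ranks from [category_rank()]. The
#' variance and the normal-approximation confidence interval come from the
#' DeLong placement-value decomposition; the interval is truncated to
#' `[0, 1]`.
#'
#' @param scores numeric (ordinal) scores; higher = more suspicious.
#' @param labels logical vector, TRUE = invasive.
#' @param level confidence level (default 0.95).
#' @return object of class `auc_result`: list with `auc`, `variance`,
#'   `ci_low`, `ci_high`, `level`, `n_positive`, `n_negative`.
#' @export
#' @examples
#' ordinal_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc  # 1
ordinal_auc <- function(scores, labels, level = 0.95) {
  comp <- delong_components(scores, labels)
  v <- 0
  if (comp$m > 1) v <- v + stats::var(comp$v10) / comp$m
  if (comp$n > 1) v <- v + stats::var(comp$v01) / comp$n
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(v)
  structure(list(auc = comp$auc, variance = v,
                 ci_low = max(0, comp$auc - half),
                 ci_high = min(1, comp$auc + half),
                 level = level, n_positive = comp$m, n_negative = comp$n),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f; %d invasive / %d noninvasive)\n",
              x$auc, 100 * x$level, x$ci_low, x$ci_high,
              x$n_positive, x$n_negative))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scoring systems evaluated on the same subjects
#' (paired design) using the DeLong structural-component estimator of
#' `var(AUC_a - AUC_b)`, which accounts for the covariance induced by the
#' shared subjects. The test statistic `z = (AUC_a - AUC_b) / sd` is
#' referred to the standard normal; p-values are two-sided. A degenerate
#' zero variance with zero difference reports p = 1.
#'
#' @param scores_a,scores_b numeric scores of the two systems on the same
#'   subjects, in the same subject order.
#' @param labels logical vector, TRUE = invasive.
#' @return object of class `delong_result`: list with `auc_a`, `auc_b`,
#'   `difference`, `variance_diff`, `z`, `p_two_sided`.
#' @export
#' @examples
#' delong_paired_test(c(1, 2, 3, 4), c(1, 2, 3, 4),
#'                    c(FALSE, FALSE, TRUE, TRUE))$p_two_sided  # 1
delong_paired_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop("scores_a and scores_b must have equal length (paired design)")
  }
  a <- delong_components(scores_a, labels)
  b <- delong_components(scores_b, labels)
  v <- 0
  if (a$m > 1) v <- v + stats::var(a$v10 - b$v10) / a$m
  if (a$n > 1) v <- v + stats::var(a$v01 - b$v01) / a$n
  diff <- a$auc - b$auc
  if (v <= 0) {
    z <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    z <- diff / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = a$auc, auc_b = b$auc, difference = diff,
                 variance_diff = v, z = z, p_two_sided = p),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong paired test: AUC_a %.3f vs AUC_b %.3f\n",
              x$auc_a, x$auc_b))
  cat(sprintf("  difference %.4f, z = %.3f, two-sided p = %.4g\n",
              x$difference, x$z, x$p_two_sided))
  invisible(x)
}
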