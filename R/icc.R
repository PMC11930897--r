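# Inter-rater agreement: ICC(2,1), two-way random effects, absolute
# agreement, single rater, from the standard mean-squares decomposition.

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Quantifies absolute agreement among k raters who each rate the same n
#' subjects (complete two-way design), treating both subjects and raters as
#' random samples. With MSR, MSC and MSE the subject, rater, and residual
#' mean squares:
#'
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`
#'
#' Absolute agreement penalises systematic rater offsets, so a constant
#' shift between raters lowers the coefficient (possibly below 0). A matrix
#' with zero total variance (all cells identical) returns 1 by convention,
#' flagged via the `degenerate` attribute.
#'
#' @param ratings numeric matrix, rows = subjects (>= 2), columns = raters
#'   (>= 2), no missing cells; typically ordinal category ranks.
#' @return object of class `icc_result`: list with `icc`, `ms` (the three
#'   mean squares), `n_subjects`, `n_raters`.
#' @export
#' @examples
#' m <- cbind(r1 = c(1, 2, 3, 4), r2 = c(1, 2, 3, 4), r3 = c(1, 2, 3, 4))
#' icc_absolute_agreement(m)$icc  # 1
icc_absolute_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (!is.numeric(ratings)) stop("ratings must be numeric")
  if (anyNA(ratings)) stop("ratings must form a complete design (no NA)")
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")

  grand <- mean(ratings)
  row_means <- rowMeans(ratings)
  col_means <- colMeans(ratings)
  ss_total <- sum((ratings - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols

  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  degenerate <- FALSE
  den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (ss_total < .Machine$double.eps * n * k) {
    icc <- 1  # all cells identical: perfect (vacuous) agreement
    degenerate <- TRUE
  } else if (abs(den) < .Machine$double.eps) {
    icc <- 0
    degenerate <- TRUE
  } else {
    icc <- (msr - mse) / den
  }
  structure(list(icc = icc, ms = c(msr = msr, msc = msc, mse = mse),
                 n_subjects = n, n_raters = k),
            degenerate = degenerate, class = "icc_result")
}

icc_band <- function(icc) {
  if (icc < 0.5) "poor" else if (icc < 0.75) "moderate"
  else if (icc < 0.9) "good" else "excellent"
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) absolute agreement: %.3f (%s consistency; %d subjects x %d raters)\n",
              x$icc, icc_band(x$icc), x$n_subjects, x$n_raters))
  if (isTRUE(attr(x, "degenerate"))) {
    cat("  note: degenerate design (no between-cell variance)\n")
  }
  invisible(x)
}
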