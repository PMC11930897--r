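# Independent oracles, deliberately coded without the rank/placement
# shortcuts used by the implementation.

# Brute-force tie-corrected Mann-Whitney AUC over all positive x negative
# pairs.
brute_force_auc <- function(scores, labels) {
  x <- scores[as.logical(labels)]
  y <- scores[!as.logical(labels)]
  gt <- outer(x, y, ">")
  eq <- outer(x, y, "==")
  (sum(gt) + 0.5 * sum(eq)) / (length(x) * length(y))
}

# Naive DeLong with explicit double loops over placement values.
naive_delong <- function(scores_a, scores_b, labels) {
  lab <- as.logical(labels)
  m <- sum(lab)
  n <- sum(!lab)
  psi <- function(x, y) if (x > y) 1 else if (x == y) 0.5 else 0
  components <- function(s) {
    x <- s[lab]
    y <- s[!lab]
    v10 <- numeric(m)
    v01 <- numeric(n)
    for (i in seq_len(m)) {
      acc <- 0
      for (j in seq_len(n)) acc <- acc + psi(x[i], y[j])
      v10[i] <- acc / n
    }
    for (j in seq_len(n)) {
      acc <- 0
      for (i in seq_len(m)) acc <- acc + psi(x[i], y[j])
      v01[j] <- acc / m
    }
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  svar <- function(u, v) {
    acc <- 0
    for (i in seq_along(u)) acc <- acc + (u[i] - mean(u)) * (v[i] - mean(v))
    acc / (length(u) - 1)
  }
  ca <- components(scores_a)
  cb <- components(scores_b)
  var_auc <- function(cc) svar(cc$v10, cc$v10) / m + svar(cc$v01, cc$v01) / n
  vdiff <- (svar(ca$v10, ca$v10) + svar(cb$v10, cb$v10) -
              2 * svar(ca$v10, cb$v10)) / m +
           (svar(ca$v01, ca$v01) + svar(cb$v01, cb$v01) -
              2 * svar(ca$v01, cb$v01)) / n
  diff <- ca$auc - cb$auc
  z <- if (vdiff > 0) diff / sqrt(vdiff) else 0
  list(auc_a = ca$auc, auc_b = cb$auc, var_a = var_auc(ca), var_b = var_auc(cb),
       difference = diff, variance_diff = vdiff, z = z,
       p = if (vdiff > 0) 2 * stats::pnorm(-abs(z)) else 1)
}

# ICC(2,1) by explicit sums (two-way random effects, absolute agreement).
icc_oracle <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(m[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(m[, j]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) ss_tot <- ss_tot + (m[i, j] - grand)^2
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
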