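# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Exhaustive two-sided Wilcoxon rank-sum p-value: enumerate every assignment
# of the pooled (tie-free) values to the two groups and compare Mann-Whitney
# U tail masses, doubling the smaller tail as wilcox.test does.
wilcox_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  n1 <- length(x)
  u_of <- function(xi) {
    xs <- pooled[xi]
    ys <- pooled[-xi]
    sum(outer(xs, ys, ">"))
  }
  us <- apply(utils::combn(n, n1), 2, u_of)
  u_obs <- sum(outer(x, y, ">"))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# AUC by explicit concordant-pair counting.
auc_enum <- function(scores, labels) {
  ca <- scores[labels == "case"]
  co <- scores[labels == "control"]
  (sum(outer(ca, co, ">")) + 0.5 * sum(outer(ca, co, "=="))) /
    (length(ca) * length(co))
}

# Exhaustive operating-point scans over candidate thresholds (rule:
# case iff score >= threshold), ties toward higher sensitivity.
scan_thresholds <- function(scores) c(Inf, sort(unique(scores), decreasing = TRUE))

sens_spec_at <- function(t, scores, labels) {
  c(sens = mean(scores[labels == "case"] >= t),
    spec = mean(scores[labels == "control"] < t))
}

youden_scan <- function(scores, labels) {
  thr <- scan_thresholds(scores)
  ss <- t(vapply(thr, sens_spec_at, numeric(2), scores, labels))
  j <- ss[, 1] + ss[, 2] - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(ss[best, 1])]
  list(threshold = thr[best], sensitivity = unname(ss[best, 1]),
       specificity = unname(ss[best, 2]), J = unname(j[best]))
}

topleft_scan <- function(scores, labels) {
  thr <- scan_thresholds(scores)
  ss <- t(vapply(thr, sens_spec_at, numeric(2), scores, labels))
  d2 <- (1 - ss[, 1])^2 + (1 - ss[, 2])^2
  best <- which(d2 <= min(d2) + 1e-12)
  best <- best[which.max(ss[best, 1])]
  list(threshold = thr[best], sensitivity = unname(ss[best, 1]),
       specificity = unname(ss[best, 2]), distance = unname(sqrt(d2[best])))
}

# Eigendecomposition of the explicitly formed sample covariance matrix.
pca_eigen_oracle <- function(x) {
  eigen(stats::cov(x), symmetric = TRUE)
}

# Closed-form two-class Fisher direction solve(Sw, mu1 - mu0), unit norm.
lda_closed_form <- function(scores, labels) {
  g <- factor(labels, levels = c("control", "case"))
  sw <- matrix(0, ncol(scores), ncol(scores))
  for (lev in levels(g)) {
    xg <- scores[g == lev, , drop = FALSE]
    cc <- sweep(xg, 2, colMeans(xg))
    sw <- sw + crossprod(cc)
  }
  dmu <- colMeans(scores[g == "case", , drop = FALSE]) -
    colMeans(scores[g == "control", , drop = FALSE])
  w <- solve(sw, dmu)
  w / sqrt(sum(w^2))
}

# Small labeled dataset builders.
toy_dataset <- function(n0 = 3, n1 = 3, p = 21, seed = 1,
                        shift_case = 0) {
  set.seed(seed)
  wn <- seq(1000, 1000 + 2 * (p - 1), by = 2)
  a <- matrix(rnorm(p * (n0 + n1), 1, 0.05), n0 + n1, p)
  a[(n0 + 1):(n0 + n1), ] <- a[(n0 + 1):(n0 + n1), ] + shift_case
  ev_dataset(wn, abs(a), sprintf("S%02d", seq_len(n0 + n1)),
             c(rep("control", n0), rep("case", n1)))
}
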