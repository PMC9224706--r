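test_that("Wilcoxon exact branch matches exhaustive enumeration", {
  # hand-checkable case: {1,2} vs {3,4} has 1 extreme assignment in 6
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  # identical multisets: no separation
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")

  set.seed(71)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      v <- sample(seq_len(50), n1 + n2)   # tie-free
      x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
      got <- wilcoxon_rank_sum(x, y)
      expect_equal(got$method, "exact")
      expect_equal(got$p_value, wilcox_enum_p(x, y), tolerance = 1e-10,
                   label = sprintf("exact p at n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("AUC equals the Mann-Whitney concordance and pROC agrees", {
  g <- function(n0, n1) factor(rep(c("control", "case"), c(n0, n1)),
                               levels = c("control", "case"))
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 11, 12), g(3, 2))$auc, 1)
  # uninformative scores
  expect_equal(roc_auc(rep(1, 8), g(4, 4))$auc, 0.5)
  # pair counting: 3 of 4 concordant pairs
  expect_equal(roc_auc(c(0.3, 0.2, 0.9, 0.25), g(2, 2))$auc, 3 / 4)

  set.seed(81)
  for (i in 1:50) {
    n0 <- sample(3:15, 1); n1 <- sample(3:15, 1)
    sc <- round(rnorm(n0 + n1), sample(1:2, 1))   # induce ties
    lab <- g(n0, n1)
    roc <- roc_auc(sc, lab)
    expect_equal(roc$auc, auc_enum(sc, lab), tolerance = 1e-12)
    # Mann-Whitney identity through the rank-based U statistic
    u <- unname(suppressWarnings(
      wilcox.test(sc[lab == "case"], sc[lab == "control"])$statistic))
    expect_equal(roc$auc, u / (n0 * n1), tolerance = 1e-12)
  }

  # cross-check AUC and DeLong CI against the independent pROC implementation
  set.seed(82)
  sc <- rnorm(30) + rep(c(0, 1), c(15, 15))
  lab <- g(15, 15)
  roc <- roc_auc(sc, lab)
  pr <- pROC::roc(response = lab, predictor = sc, levels = c("control", "case"),
                  direction = "<", quiet = TRUE)
  expect_equal(roc$auc, as.numeric(pr$auc), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(c(roc$ci_low, roc$ci_high), ci[c(1, 3)], tolerance = 1e-10)
})

test_that("ROC is a step function invariant under increasing transforms", {
  set.seed(83)
  sc <- rnorm(24)
  lab <- factor(rep(c("control", "case"), 12), levels = c("control", "case"))
  roc <- roc_auc(sc, lab)
  expect_equal(roc$sensitivity[1], 0)
  expect_equal(roc$specificity[1], 1)
  expect_equal(roc$sensitivity[length(roc$sensitivity)], 1)
  expect_equal(roc$specificity[length(roc$specificity)], 0)
  expect_true(all(diff(roc$sensitivity) >= 0))
  expect_true(all(diff(roc$specificity) <= 0))
  trans <- roc_auc(exp(2 * sc) + 1, lab)
  expect_equal(trans$auc, roc$auc, tolerance = 1e-12)
  expect_equal(trans$sensitivity, roc$sensitivity)
  expect_equal(trans$specificity, roc$specificity)
})

test_that("operating points match brute-force threshold scans", {
  g <- function(n0, n1) factor(rep(c("control", "case"), c(n0, n1)),
                               levels = c("control", "case"))
  perf <- roc_auc(c(1, 2, 10, 11), g(2, 2))
  yj <- youden_threshold(perf)
  expect_equal(yj$J, 1)
  expect_equal(yj$sensitivity, 1)
  expect_equal(yj$specificity, 1)
  expect_equal(closest_topleft_threshold(perf)$distance, 0)
  flat <- roc_auc(rep(2, 6), g(3, 3))
  expect_equal(youden_threshold(flat)$J, 0)

  set.seed(91)
  for (i in 1:25) {
    sc <- round(rnorm(40), 1)
    lab <- g(20, 20)
    roc <- roc_auc(sc, lab)
    yj <- youden_threshold(roc)
    or_y <- youden_scan(sc, lab)
    expect_equal(yj$J, or_y$J, tolerance = 1e-12)
    expect_equal(yj$sensitivity, or_y$sensitivity)
    expect_equal(yj$specificity, or_y$specificity)
    tl <- closest_topleft_threshold(roc)
    or_t <- topleft_scan(sc, lab)
    expect_equal(tl$distance, or_t$distance, tolerance = 1e-12)
    expect_equal(tl$sensitivity, or_t$sensitivity)
  }
})

test_that("logistic fits are maximum likelihood with symmetry and separation contracts", {
  # data invariant under (x, group) -> (-x, swapped) force a zero intercept
  x <- data.frame(m = c(-3, -1, 2, 3, 1, -2))
  lab <- rep(c("control", "case"), each = 3)
  fit <- fit_logistic(x, lab)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0, tolerance = 1e-6)

  # optimum beats a coefficient grid (independent likelihood oracle)
  set.seed(101)
  xv <- rnorm(25)
  y <- as.integer(runif(25) < plogis(0.4 + 0.8 * xv))
  lab2 <- ifelse(y == 1, "case", "control")
  fit2 <- fit_logistic(data.frame(m = xv), lab2)
  loglik <- function(b0, b1) sum(y * (b0 + b1 * xv) - log1p(exp(b0 + b1 * xv)))
  grid <- expand.grid(b0 = seq(-4, 4, length.out = 100),
                      b1 = seq(-4, 4, length.out = 100))
  best_grid <- max(mapply(loglik, grid$b0, grid$b1))
  expect_gte(loglik(fit2$coefficients[1], fit2$coefficients[2]) + 1e-9,
             best_grid)

  # perfect separation is flagged, collinear designs are refused
  xs <- data.frame(m = c(1, 2, 3, 10, 11, 12, 13))
  labs <- rep(c("control", "case"), c(3, 4))
  expect_true(fit_logistic(xs, labs)$separation)
  dup <- data.frame(a = rnorm(12), lab = rep(c("control", "case"), 6))
  dup$b <- 2 * dup$a
  expect_error(fit_logistic(dup[c("a", "b")], dup$lab), "degenerate design")
  expect_error(fit_logistic(data.frame(k = rep(1, 8)),
                            rep(c("control", "case"), 4)), "constant")
})

test_that("stepwise selection keeps informative markers and decreases AIC", {
  set.seed(111)
  n <- 40
  lab <- rep(c("control", "case"), each = n / 2)
  x <- data.frame(signal = rnorm(n) + 2 * (lab == "case"),
                  noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  sel <- stepwise_select(x, lab)
  expect_true("signal" %in% sel$markers)
  expect_true(all(diff(sel$trace$aic) < 0))

  # single-marker combination has the marker's own AUC (monotone invariance)
  one <- fit_logistic(x["signal"], lab)
  croc <- combined_marker_roc(one, x, lab)
  expect_equal(croc$auc, roc_auc(x$signal, lab)$auc, tolerance = 1e-12)

  # two independent informative markers: combining does not lose discrimination
  set.seed(112)
  n2 <- 400
  lab2 <- rep(c("control", "case"), each = n2 / 2)
  x2 <- data.frame(m1 = rnorm(n2) + 1.2 * (lab2 == "case"),
                   m2 = rnorm(n2) + 1.2 * (lab2 == "case"))
  both <- fit_logistic(x2, lab2)
  auc_comb <- combined_marker_roc(both, x2, lab2)$auc
  expect_gte(auc_comb + 1e-9,
             max(roc_auc(x2$m1, lab2)$auc, roc_auc(x2$m2, lab2)$auc))
})
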