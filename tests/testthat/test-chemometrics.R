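test_that("PCA matches an explicit covariance eigendecomposition", {
  set.seed(21)
  x <- matrix(rnorm(20), 5, 4)
  pca <- fit_pca(x, n_components = 3)
  oracle <- pca_eigen_oracle(x)
  keep <- oracle$values > 1e-12
  expect_equal(pca$eigenvalues[keep], oracle$values[keep], tolerance = 1e-8)
  for (k in 1:3) {
    # eigenvectors agree up to sign
    expect_equal(abs(sum(pca$loadings[, k] * oracle$vectors[, k])), 1,
                 tolerance = 1e-8)
  }
  # orthonormal loadings, nonincreasing eigenvalues, centered scores
  expect_equal(crossprod(pca$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  expect_equal(colMeans(pca$scores), rep(0, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # total retained score variance equals the retained eigenvalues
  expect_equal(apply(pca$scores, 2, var), pca$eigenvalues[1:3],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(fit_pca(x, 5), "n_components")
})

test_that("rank-1 data put all variance on PC1", {
  t_ <- seq(-1, 1, length.out = 9)
  x <- cbind(2 * t_, -t_) + 5
  pca <- fit_pca(x, 1)
  expect_equal(pca$eigenvalues[1] / sum(pca$eigenvalues), 1, tolerance = 1e-12)
})

test_that("LDA recovers the closed-form Fisher direction", {
  set.seed(31)
  n <- 40
  scores <- rbind(matrix(rnorm(2 * n, 0, 1), n, 2),
                  sweep(matrix(rnorm(2 * n, 0, 1), n, 2), 2, c(4, 0), "+"))
  labels <- rep(c("control", "case"), each = n)
  fit <- fit_lda(scores, labels)
  # isotropic scatter, separation along e1 -> direction e1
  expect_equal(abs(fit$direction[1]), 1, tolerance = 0.05)
  w0 <- lda_closed_form(scores, labels)
  expect_equal(fisher_criterion(fit$direction, scores, labels),
               fisher_criterion(w0, scores, labels), tolerance = 1e-8)
  # optimality spot-check against 1000 random unit directions
  set.seed(32)
  jbest <- fisher_criterion(fit$direction, scores, labels)
  for (i in 1:1000) {
    u <- rnorm(2); u <- u / sqrt(sum(u^2))
    expect_lte(fisher_criterion(u, scores, labels), jbest + 1e-10)
  }
  # sign convention: case mean above control mean
  expect_gt(fit$class_means["case"], fit$class_means["control"])
  # agreement with MASS::lda up to scale/sign
  ml <- MASS::lda(scores, grouping = labels)
  cosang <- abs(sum(fit$direction * ml$scaling) /
                  sqrt(sum(ml$scaling^2)))
  expect_equal(cosang, 1, tolerance = 1e-6)

  same <- rbind(scores[1:n, ], scores[1:n, ])
  expect_error(fit_lda(same, labels), "no separation")
  expect_error(fit_lda(scores[1:n, ], rep("control", n)), "both classes")
})

test_that("band-shape LD1 scores detect a planted peak shift", {
  wn <- seq(1400, 1800, 2)
  gauss <- function(ctr) exp(-(wn - ctr)^2 / (2 * 20^2))
  set.seed(41)
  n0 <- 10; n1 <- 10
  a <- rbind(
    t(replicate(n0, gauss(1655) + rnorm(length(wn), 0, 0.01))),
    t(replicate(n1, gauss(1663) + rnorm(length(wn), 0, 0.01)))
  )
  d <- ev_dataset(wn, a, sprintf("S%02d", 1:(n0 + n1)),
                  rep(c("control", "case"), c(n0, n1)))
  sc <- pca_lda_scores(d, band("amide", 1470, 1700))
  expect_gt(mean(sc[d$group == "case"]), mean(sc[d$group == "control"]))
  # standardized: zero mean, unit sd
  expect_equal(mean(sc), 0, tolerance = 1e-10)
  expect_equal(sd(sc), 1, tolerance = 1e-10)
  # permutation equivariance: permuting subjects permutes scores
  perm <- sample(n_subjects(d))
  dp <- ev_dataset(d$wavenumber, d$absorbance[perm, ], d$subject_id[perm],
                   as.character(d$group)[perm])
  scp <- pca_lda_scores(dp, band("amide", 1470, 1700))
  expect_equal(scp[d$subject_id], sc, tolerance = 1e-8)
})

test_that("LOOCV refits the whole chain per fold", {
  d <- toy_dataset(n0 = 10, n1 = 10, p = 41, seed = 51, shift_case = 0.5)
  w <- band("w", min(d$wavenumber), max(d$wavenumber))
  cv <- loocv_classify(d, w)
  expect_equal(cv$n_folds, 20L)
  expect_equal(nrow(cv$predictions), 20L)
  expect_equal(cv$tp + cv$fn, sum(d$group == "case"))
  expect_equal(cv$tn + cv$fp, sum(d$group == "control"))
  expect_equal(cv$sensitivity, cv$tp / (cv$tp + cv$fn))
  expect_equal(cv$accuracy, (cv$tp + cv$tn) / 20)

  # overwhelming band-shape separation classifies perfectly (the chain
  # area-normalizes, so only shape differences can separate groups)
  wn2 <- d$wavenumber
  set.seed(52)
  shapes <- rbind(
    t(replicate(8, exp(-(wn2 - 1015)^2 / 200) + rnorm(41, 0, 0.01) + 0.2)),
    t(replicate(8, exp(-(wn2 - 1065)^2 / 200) + rnorm(41, 0, 0.01) + 0.2))
  )
  dbig <- ev_dataset(wn2, abs(shapes), sprintf("T%02d", 1:16),
                     rep(c("control", "case"), each = 8))
  expect_equal(loocv_classify(dbig, w)$accuracy, 1)

  # leakage guard: per-fold PCA refit must differ from the full-data-PCA
  # variant on a dataset containing an outlier subject
  dout <- toy_dataset(n0 = 6, n1 = 6, p = 41, seed = 53, shift_case = 0.3)
  dout$absorbance[1, ] <- dout$absorbance[1, ] + 30 * sin(seq(0, 6, length.out = 41))
  cv_refit <- loocv_classify(dout, w, refit_pca = TRUE)
  cv_leak <- loocv_classify(dout, w, refit_pca = FALSE)
  expect_false(isTRUE(all.equal(cv_refit$predictions$ld1,
                                cv_leak$predictions$ld1)))
})

test_that("LOOCV needs both classes retained in every training fold", {
  d <- toy_dataset(n0 = 1, n1 = 5, p = 21, seed = 61, shift_case = 1)
  w <- band("w", min(d$wavenumber), max(d$wavenumber))
  expect_error(loocv_classify(d, w), "at least 2")
})
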