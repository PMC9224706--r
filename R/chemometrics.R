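#' Principal component analysis of a spectral matrix
#'
#' Eigendecomposition of the sample covariance of mean-centered rows
#' (subjects), computed via [stats::prcomp()]. Components are ordered by
#' decreasing eigenvalue; loadings are orthonormal.
#'
#' @param x Numeric matrix, subjects x wavenumbers, >= 2 rows.
#' @param n_components Number of components to retain;
#'   `<= min(nrow - 1, ncol)`.
#' @return An object of class `pca_model`: `center` (column means),
#'   `loadings` (wavenumbers x components, orthonormal columns),
#'   `eigenvalues` (all sample-covariance eigenvalues, nonincreasing),
#'   `scores` (subjects x components), `n_components`.
#' @export
fit_pca <- function(x, n_components = 2L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least 2 rows")
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (n_components > kmax) {
    stop("n_components = ", n_components, " exceeds min(rows-1, cols) = ", kmax)
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  structure(
    list(center = p$center,
         loadings = p$rotation[, seq_len(n_components), drop = FALSE],
         eigenvalues = p$sdev^2,
         scores = p$x[, seq_len(n_components), drop = FALSE],
         n_components = as.integer(n_components)),
    class = "pca_model"
  )
}

#' Project new spectra onto a fitted PCA basis
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param x Matrix (or vector) of spectra on the training wavenumber grid.
#' @return Score matrix, rows x `n_components`.
#' @export
project_pca <- function(model, x) {
  x <- matrix(x, ncol = length(model$center), byrow = FALSE)
  sweep(x, 2, model$center) %*% model$loadings
}

#' Two-class Fisher linear discriminant in PC-score space
#'
#' Finds the unit direction `w` maximizing the Fisher criterion
#' `J(w) = (w' Sb w) / (w' Sw w)`; for two classes the maximizer is
#' `w` proportional to `solve(Sw, mu_case - mu_control)`. `Sw` is the pooled
#' within-class scatter; when near-singular a ridge
#' `eps = 1e-8 * trace(Sw) / k` is added. The sign of `w` is fixed so the
#' case group has the higher mean LD1 score.
#'
#' @param scores Numeric matrix, subjects x k (typically PC scores).
#' @param labels Factor/vector with both `"control"` and `"case"` present.
#' @return An object of class `lda_model`: `direction` (unit vector),
#'   `class_means` (mean LD1 per group), `threshold` (midpoint of the class
#'   means), `J` (Fisher criterion at the fit).
#' @export
fit_lda <- function(scores, labels) {
  scores <- as.matrix(scores)
  g <- as_group(labels)
  if (anyNA(g)) stop("labels must be control/case with no unknowns")
  if (length(unique(g)) < 2L) stop("both classes must be present")
  m0 <- colMeans(scores[g == "control", , drop = FALSE])
  m1 <- colMeans(scores[g == "case", , drop = FALSE])
  dmu <- m1 - m0
  scale_ref <- sqrt(mean(colMeans(scores^2)))
  if (sqrt(sum(dmu^2)) <= 1e-12 * max(scale_ref, 1)) {
    stop("no separation: identical class means, Fisher criterion is 0 for all directions")
  }
  sw <- within_scatter(scores, g)
  k <- ncol(scores)
  if (rcond_sym(sw) < 1e-10) {
    sw <- sw + diag(1e-8 * sum(diag(sw)) / k, k)
  }
  w <- solve(sw, dmu)
  w <- w / sqrt(sum(w^2))
  ld1 <- drop(scores %*% w)
  if (mean(ld1[g == "case"]) < mean(ld1[g == "control"])) {
    w <- -w
    ld1 <- -ld1
  }
  mu0 <- mean(ld1[g == "control"]); mu1 <- mean(ld1[g == "case"])
  structure(
    list(direction = w,
         class_means = c(control = mu0, case = mu1),
         threshold = (mu0 + mu1) / 2,
         J = fisher_criterion(w, scores, g)),
    class = "lda_model"
  )
}

within_scatter <- function(scores, g) {
  sw <- matrix(0, ncol(scores), ncol(scores))
  for (lev in levels(g)) {
    xg <- scores[g == lev, , drop = FALSE]
    cc <- sweep(xg, 2, colMeans(xg))
    sw <- sw + crossprod(cc)
  }
  sw
}

between_scatter <- function(scores, g) {
  mu <- colMeans(scores)
  sb <- matrix(0, ncol(scores), ncol(scores))
  for (lev in levels(g)) {
    xg <- scores[g == lev, , drop = FALSE]
    d <- colMeans(xg) - mu
    sb <- sb + nrow(xg) * tcrossprod(d)
  }
  sb
}

#' Fisher criterion of a direction
#'
#' `J(w) = (w' Sb w)/(w' Sw w)` for given scores and labels; used to verify
#' optimality of the fitted discriminant.
#'
#' @param w Direction vector.
#' @param scores Subjects x k matrix.
#' @param labels control/case labels.
#' @return Numeric scalar.
#' @export
fisher_criterion <- function(w, scores, labels) {
  g <- as_group(labels)
  scores <- as.matrix(scores)
  num <- drop(t(w) %*% between_scatter(scores, g) %*% w)
  den <- drop(t(w) %*% within_scatter(scores, g) %*% w)
  num / den
}

rcond_sym <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) 0 else min(abs(ev)) / max(abs(ev))
}

#' PCA-LDA band-shape score per subject
#'
#' The band-shape biomarker: each spectrum is restricted to the window,
#' linearly baseline-corrected and area-normalized; the cohort is projected
#' onto its first `n_components` principal components, a two-class Fisher
#' discriminant is fitted in score space, and each subject's LD1 projection
#' is standardized to zero mean and unit standard deviation, with the sign
#' fixed so the case group scores higher.
#'
#' @param dataset A labeled [ev_dataset()] on a common grid.
#' @param window A [band()].
#' @param n_components Number of principal components (default 2).
#' @return Named numeric vector of standardized LD1 scores (names =
#'   subject ids).
#' @export
pca_lda_scores <- function(dataset, window, n_components = 2L) {
  check_groups(dataset, min_per_group = 2L)
  shaped <- preprocess_band(dataset, window, normalize_after = TRUE)
  pca <- fit_pca(shaped$absorbance, n_components)
  lda <- fit_lda(pca$scores, shaped$group)
  ld1 <- drop(pca$scores %*% lda$direction)
  ld1 <- (ld1 - mean(ld1)) / stats::sd(ld1)
  if (mean(ld1[shaped$group == "case"]) < mean(ld1[shaped$group == "control"])) {
    ld1 <- -ld1
  }
  stats::setNames(ld1, dataset$subject_id)
}

#' Leave-one-out cross-validated PCA-LDA classification
#'
#' For each held-out subject the entire chain — band restriction, baseline
#' correction, area normalization (per-spectrum, leakage-free), centering,
#' PCA, LDA, and the classification threshold at the midpoint of the two
#' training class-mean LD1 scores — is refitted on the remaining n-1
#' subjects; the held-out spectrum is then projected and classified. With
#' `refit_pca = FALSE` the PCA basis is fitted once on all subjects and only
#' the LDA is refitted per fold (the leakage-prone variant, kept for
#' comparison).
#'
#' @param dataset A labeled [ev_dataset()], n >= 4, both classes present.
#' @param window A [band()].
#' @param n_components Number of principal components (default 2).
#' @param refit_pca Refit the PCA inside each fold (default `TRUE`).
#' @return An object of class `cv_report`: confusion counts (`tp`, `fp`,
#'   `tn`, `fn`), `sensitivity`, `specificity`, `accuracy`, and a
#'   `predictions` tibble with one row per fold.
#' @export
loocv_classify <- function(dataset, window, n_components = 2L,
                           refit_pca = TRUE) {
  check_groups(dataset, min_per_group = 2L)
  n <- n_subjects(dataset)
  if (n < 4L) stop("LOOCV needs at least 4 subjects")
  shaped <- preprocess_band(dataset, window, normalize_after = TRUE)
  x <- shaped$absorbance
  g <- shaped$group
  full_pca <- if (!refit_pca) fit_pca(x, n_components) else NULL
  pred <- character(n)
  score <- numeric(n)
  for (i in seq_len(n)) {
    gtr <- g[-i]
    if (length(unique(gtr)) < 2L) {
      stop("training fold ", i, " lost a class entirely")
    }
    xtr <- x[-i, , drop = FALSE]
    pca <- if (refit_pca) fit_pca(xtr, n_components) else full_pca
    str_ <- if (refit_pca) pca$scores else project_pca(pca, xtr)
    lda <- fit_lda(str_, gtr)
    s_i <- drop(project_pca(pca, x[i, ]) %*% lda$direction)
    score[i] <- s_i
    pred[i] <- if (s_i > lda$threshold) "case" else "control"
  }
  tp <- sum(pred == "case" & g == "case")
  fn <- sum(pred == "control" & g == "case")
  tn <- sum(pred == "control" & g == "control")
  fp <- sum(pred == "case" & g == "control")
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         accuracy = (tp + tn) / n,
         predictions = tibble::tibble(
           subject_id = dataset$subject_id, group = g,
           ld1 = score, predicted = factor(pred, levels = c("control", "case"))),
         n_folds = n, band = window$name, refit_pca = refit_pca),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> band %s: %d folds | sens %.3f spec %.3f acc %.3f (tp %d fp %d tn %d fn %d)\n",
    x$band, x$n_folds, x$sensitivity, x$specificity, x$accuracy,
    x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}
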