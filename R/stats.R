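#' Wilcoxon rank-sum test between control and case values
#'
#' Two-sided Wilcoxon (Mann-Whitney) test via [stats::wilcox.test()]: exact
#' enumeration when both samples are small and tie-free, otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param x Control values.
#' @param y Case values.
#' @return A list: `statistic` (Mann-Whitney U of `x` vs `y`), `p_value`,
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) < 50 && length(y) < 50
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic),
       p_value = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Empirical ROC curve with AUC and confidence interval
#'
#' The empirical ROC over all distinct score thresholds, classifying a
#' subject as case when `score >= threshold`. The AUC is the
#' Mann-Whitney concordance `(# case > control pairs + 0.5 * ties) /
#' (n_case * n_control)`, i.e. the probability that a random case outscores
#' a random control. The 95% CI is computed by DeLong's method (default,
#' deterministic) or by a stratified bootstrap of the AUC.
#'
#' @param scores Numeric marker values, higher = more case-like (use
#'   `orient = TRUE` to auto-flip markers where controls score higher).
#' @param labels control/case labels, both present.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param orient If `TRUE`, negate the scores when the raw AUC < 0.5 so the
#'   reported AUC is >= 0.5; the applied direction is recorded.
#' @param n_boot Bootstrap replicates (bootstrap CI only).
#' @param conf Confidence level (default 0.95).
#' @return An object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity` (step-function coordinates from (0,0) to (1,1)), `auc`,
#'   `ci_low`, `ci_high`, `n_case`, `n_control`, `direction` (+1 untouched,
#'   -1 negated), plus the (oriented) `scores` and `labels`.
#' @export
roc_auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                    orient = FALSE, n_boot = 2000L, conf = 0.95) {
  ci_method <- match.arg(ci_method)
  g <- as_group(labels)
  if (anyNA(g)) stop("labels must be control/case with no unknowns")
  if (length(unique(g)) < 2L) stop("both classes must be present")
  stopifnot(length(scores) == length(g), all(is.finite(scores)))
  direction <- 1
  if (orient && auc_mw(scores, g) < 0.5) {
    scores <- -scores
    direction <- -1
  }
  ca <- scores[g == "case"]
  co <- scores[g == "control"]
  # step-function coordinates: thresholds descending through distinct scores
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(ca >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(co < t), numeric(1))
  auc <- auc_mw(scores, g)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (ci_method == "delong") {
    v <- delong_variance(ca, co)
    ci <- auc + c(-1, 1) * z * sqrt(v)
  } else {
    reps <- vapply(seq_len(n_boot), function(i) {
      auc_pairs(sample(ca, replace = TRUE), sample(co, replace = TRUE))
    }, numeric(1))
    ci <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)
  }
  structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec,
         auc = auc, ci_low = max(0, ci[1]), ci_high = min(1, ci[2]),
         ci_method = ci_method, n_case = length(ca), n_control = length(co),
         direction = direction, scores = scores, labels = g),
    class = "roc_result"
  )
}

# AUC as the Mann-Whitney concordance via midranks (handles ties)
auc_mw <- function(scores, g) {
  r <- rank(scores)
  n1 <- sum(g == "case"); n0 <- sum(g == "control")
  (sum(r[g == "case"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# AUC by explicit pair counting (used by the bootstrap resampler)
auc_pairs <- function(ca, co) {
  (sum(outer(ca, co, ">")) + 0.5 * sum(outer(ca, co, "=="))) /
    (length(ca) * length(co))
}

# DeLong variance of the empirical AUC
delong_variance <- function(ca, co) {
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(ca, function(x) mean(psi(x, co)), numeric(1))
  v01 <- vapply(co, function(y) mean(psi(ca, y)), numeric(1))
  stats::var(v10) / length(ca) + stats::var(v01) / length(co)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d%% CI %.3f-%.3f, %s), %d case / %d control%s\n",
              x$auc, 95L, x$ci_low, x$ci_high, x$ci_method,
              x$n_case, x$n_control,
              if (x$direction < 0) ", scores negated" else ""))
  invisible(x)
}

#' Youden-optimal operating point
#'
#' The threshold maximizing Youden's J = sensitivity + specificity - 1 over
#' the ROC's thresholds; ties are broken toward the higher sensitivity.
#'
#' @param roc A [roc_auc()] result.
#' @return A list: `threshold`, `sensitivity`, `specificity`, `J`.
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(roc$sensitivity[best])]
  list(threshold = roc$thresholds[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best],
       J = j[best])
}

#' Closest-to-top-left operating point
#'
#' The threshold minimizing the squared ROC distance to the perfect
#' classifier, `(1 - sens)^2 + (1 - spec)^2`; ties toward the higher
#' sensitivity.
#'
#' @param roc A [roc_auc()] result.
#' @return A list: `threshold`, `sensitivity`, `specificity`, `distance`.
#' @export
closest_topleft_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  d2 <- (1 - roc$sensitivity)^2 + (1 - roc$specificity)^2
  best <- which(d2 <= min(d2) + 1e-12)
  best <- best[which.max(roc$sensitivity[best])]
  list(threshold = roc$thresholds[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best],
       distance = sqrt(d2[best]))
}

#' Multivariate logistic regression on marker columns
#'
#' Maximum-likelihood binomial fit (iteratively reweighted least squares via
#' [stats::glm()]) of case membership on the given markers. Complete or
#' quasi-complete separation is detected — a coefficient exceeding 15 in
#' magnitude on internally standardized inputs, or IRLS non-convergence —
#' and flagged in `separation`/`converged`.
#'
#' @param features Data frame of numeric marker columns (or a feature table;
#'   non-marker columns `subject_id`/`group` are dropped).
#' @param labels control/case labels.
#' @param markers Optional character vector selecting columns.
#' @return An object of class `logistic_model`: `markers`, `coefficients`
#'   (incl. intercept), `converged`, `separation`, `aic`, `fit` (the glm).
#' @export
fit_logistic <- function(features, labels, markers = NULL) {
  x <- marker_frame(features, markers)
  g <- as_group(labels)
  if (anyNA(g)) stop("labels must be control/case with no unknowns")
  y <- as.integer(g == "case")
  if (length(y) <= ncol(x) + 1L) {
    stop("need n > number of coefficients (n = ", length(y),
         ", markers = ", ncol(x), ")")
  }
  const <- vapply(x, function(col) stats::sd(col) == 0, logical(1))
  if (any(const)) {
    stop("constant marker column(s): ", paste(names(x)[const], collapse = ", "))
  }
  if (qr(cbind(1, as.matrix(x)))$rank < ncol(x) + 1L) {
    stop("degenerate design matrix: collinear marker columns")
  }
  d <- cbind(x, .y = y)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = d, family = stats::binomial(),
               control = stats::glm.control(maxit = 100, epsilon = 1e-8))
  )
  sds <- vapply(x, stats::sd, numeric(1))
  std_coef <- stats::coef(fit)[-1] * sds
  separation <- any(abs(std_coef) > 15) || !fit$converged ||
    any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
  structure(
    list(markers = names(x), coefficients = stats::coef(fit),
         converged = fit$converged && !separation,
         separation = separation, aic = stats::AIC(fit), fit = fit),
    class = "logistic_model"
  )
}

marker_frame <- function(features, markers = NULL) {
  x <- as.data.frame(features)
  x <- x[, setdiff(names(x), c("subject_id", "group")), drop = FALSE]
  if (!is.null(markers)) {
    missing <- setdiff(markers, names(x))
    if (length(missing)) stop("unknown marker(s): ", paste(missing, collapse = ", "))
    x <- x[, markers, drop = FALSE]
  }
  not_num <- !vapply(x, is.numeric, logical(1))
  if (any(not_num)) stop("non-numeric marker column(s): ",
                         paste(names(x)[not_num], collapse = ", "))
  x
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> %s | AIC %.2f%s\n",
              if (length(x$markers)) paste(x$markers, collapse = " + ")
              else "(intercept only)",
              x$aic,
              if (x$separation) " | SEPARATION FLAGGED" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Stepwise logistic marker selection by AIC
#'
#' Bidirectional stepwise search with [stats::step()] starting from the full
#' model over all candidate markers, minimizing AIC. Deterministic given the
#' input column order. The selection trace (one row per accepted step, AIC
#' strictly decreasing) is returned alongside the final model.
#'
#' @param features Data frame / feature table with >= 2 candidate marker
#'   columns.
#' @param labels control/case labels.
#' @param markers Optional character vector of candidate columns.
#' @return A `logistic_model` whose `markers` are the selected subset, with
#'   an extra `trace` data frame (columns `step`, `aic`).
#' @export
stepwise_select <- function(features, labels, markers = NULL) {
  x <- marker_frame(features, markers)
  if (ncol(x) < 2L) stop("stepwise selection needs >= 2 candidate markers")
  g <- as_group(labels)
  y <- as.integer(g == "case")
  d <- cbind(x, .y = y)
  full <- suppressWarnings(
    stats::glm(.y ~ ., data = d, family = stats::binomial(),
               control = stats::glm.control(maxit = 100, epsilon = 1e-8))
  )
  sel <- suppressWarnings(
    stats::step(full, scope = list(lower = .y ~ 1, upper = stats::formula(full)),
                direction = "both", trace = 0, k = 2)
  )
  kept <- setdiff(names(stats::coef(sel)), "(Intercept)")
  # backticked names may come back from step() on non-syntactic columns
  kept <- gsub("^`|`$", "", kept)
  out <- if (length(kept)) {
    fit_logistic(x[, kept, drop = FALSE], g)
  } else {
    structure(
      list(markers = character(0),
           coefficients = stats::coef(sel),
           converged = sel$converged, separation = FALSE,
           aic = stats::AIC(sel), fit = sel),
      class = "logistic_model"
    )
  }
  out$trace <- data.frame(step = rownames(sel$anova), aic = sel$anova$AIC,
                          row.names = NULL)
  out
}

#' ROC of a fitted marker combination
#'
#' ROC/AUC of the linear predictor of a fitted logistic model (equivalently
#' of the fitted probabilities — ROC is invariant under strictly increasing
#' transforms).
#'
#' @param model A `logistic_model`.
#' @param features Feature table holding the model's marker columns.
#' @param labels control/case labels.
#' @param ci_method Passed to [roc_auc()].
#' @return A [roc_auc()] result.
#' @export
combined_marker_roc <- function(model, features, labels,
                                ci_method = "delong") {
  stopifnot(inherits(model, "logistic_model"))
  x <- marker_frame(features,
                    if (length(model$markers)) model$markers else NULL)
  lp <- if (length(model$markers)) {
    drop(as.matrix(x[, model$markers, drop = FALSE]) %*%
           model$coefficients[model$markers]) + model$coefficients["(Intercept)"]
  } else {
    rep(model$coefficients[["(Intercept)"]], nrow(x))
  }
  roc_auc(lp, labels, ci_method = ci_method)
}
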