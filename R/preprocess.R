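#' Subtract a linear baseline over a band
#'
#' Restricts the spectrum to the closed window and removes the straight line
#' through the absorbance values at the two window anchors. With the default
#' `anchor_k = 1` the anchor values are the single grid points nearest `lo`
#' and `hi` and the corrected absorbance at both anchors is exactly zero;
#' `anchor_k = 3` averages three grid points around each anchor for noise
#' robustness. The operation is idempotent.
#'
#' @param spectrum An [ev_spectrum()].
#' @param window A [band()]; must contain at least 3 grid points.
#' @param anchor_k Odd number of grid points averaged at each anchor.
#' @return The corrected window slice as an [ev_spectrum()].
#' @export
subtract_linear_baseline <- function(spectrum, window, anchor_k = 1L) {
  stopifnot(inherits(spectrum, "ev_spectrum"), inherits(window, "band_definition"))
  idx <- band_index(spectrum$wavenumber, window)
  if (length(idx) < 3L) {
    stop("band ", window$name, " covers ", length(idx),
         " grid points; need at least 3")
  }
  x <- spectrum$wavenumber[idx]
  y <- spectrum$absorbance[idx]
  n <- length(x)
  k <- min(as.integer(anchor_k), n %/% 2)
  a_lo <- mean(y[seq_len(k)])
  a_hi <- mean(y[seq.int(n - k + 1L, n)])
  x_lo <- mean(x[seq_len(k)])
  x_hi <- mean(x[seq.int(n - k + 1L, n)])
  slope <- (a_hi - a_lo) / (x_hi - x_lo)
  baseline <- a_lo + slope * (x - x_lo)
  out <- spectrum
  out$wavenumber <- x
  out$absorbance <- y - baseline
  out
}

#' Normalize a spectrum
#'
#' * `area`: divide by the trapezoid integral of |A| so that the integrated
#'   absolute absorbance over the spectrum's grid is 1.
#' * `vector`: divide by the Euclidean norm so that sum(A^2) = 1.
#' * `max`: divide by the maximum so that max(A) = 1.
#'
#' @param spectrum An [ev_spectrum()].
#' @param method `"area"` (default), `"vector"` or `"max"`.
#' @return The normalized [ev_spectrum()].
#' @export
normalize <- function(spectrum, method = c("area", "vector", "max")) {
  method <- match.arg(method)
  stopifnot(inherits(spectrum, "ev_spectrum"))
  a <- spectrum$absorbance
  denom <- switch(method,
    area   = pracma::trapz(spectrum$wavenumber, abs(a)),
    vector = sqrt(sum(a^2)),
    max    = max(a)
  )
  if (!is.finite(denom) || denom <= 0) {
    stop("cannot ", method, "-normalize: norm is ", format(denom))
  }
  spectrum$absorbance <- a / denom
  spectrum
}

#' Baseline-correct (and optionally normalize) every spectrum over a band
#'
#' Restricts each spectrum to the window, subtracts the linear baseline, and
#' when `normalize_after = TRUE` re-normalizes the band slice to unit
#' integrated absolute absorbance. This is the per-band preprocessing applied
#' before band-shape (PCA-LDA) analysis; the whole-spectrum stage is the same
#' call with [full_range_band()].
#'
#' @param dataset An [ev_dataset()] on a common grid.
#' @param window A [band()].
#' @param normalize_after Apply area normalization within the band.
#' @param anchor_k Passed to [subtract_linear_baseline()].
#' @return An [ev_dataset()] restricted to the window grid.
#' @export
preprocess_band <- function(dataset, window, normalize_after = TRUE,
                            anchor_k = 1L) {
  stopifnot(inherits(dataset, "ev_dataset"))
  out <- lapply(seq_len(n_subjects(dataset)), function(i) {
    s <- subtract_linear_baseline(get_spectrum(dataset, i), window, anchor_k)
    if (normalize_after) s <- normalize(s, "area")
    s
  })
  bind_spectra(out)
}

#' Group mean spectrum with pointwise 95% confidence band
#'
#' Pointwise mean absorbance for one group together with
#' mean +/- t(0.975, n-1) * SEM at each wavenumber.
#'
#' @param dataset A labeled [ev_dataset()].
#' @param group `"control"` or `"case"`; needs >= 2 subjects.
#' @param conf Confidence level (default 0.95).
#' @return A [tibble::tibble()] with columns `wavenumber`, `mean`, `lower`,
#'   `upper`.
#' @export
group_mean_spectrum <- function(dataset, group, conf = 0.95) {
  stopifnot(inherits(dataset, "ev_dataset"))
  group <- match.arg(group, c("control", "case"))
  rows <- which(dataset$group == group)
  if (length(rows) < 2L) {
    stop("group '", group, "' has ", length(rows),
         " subject(s); need >= 2 for a confidence band")
  }
  a <- dataset$absorbance[rows, , drop = FALSE]
  m <- colMeans(a)
  sem <- apply(a, 2, stats::sd) / sqrt(nrow(a))
  tq <- stats::qt(1 - (1 - conf) / 2, df = nrow(a) - 1L)
  tibble::tibble(wavenumber = dataset$wavenumber, mean = m,
                 lower = m - tq * sem, upper = m + tq * sem)
}
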