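#' Integrated band area
#'
#' Trapezoid integral of the (by default linearly baseline-corrected)
#' absorbance over a closed wavenumber window, in absorbance * cm^-1.
#' Trapezoid integration is exact for piecewise-linear spectra. Negative
#' corrected absorbance is integrated as-is unless `clip_negative = TRUE`
#' (a sensitivity-analysis option: clipping biases small bands upward).
#'
#' @param spectrum An [ev_spectrum()] covering the window.
#' @param window A [band()].
#' @param correct_baseline Subtract the linear baseline first (set `FALSE`
#'   when the band has already been corrected, to avoid double correction).
#' @param clip_negative Truncate negative corrected absorbance at zero.
#' @param anchor_k Passed to [subtract_linear_baseline()].
#' @return Numeric scalar area.
#' @export
band_area <- function(spectrum, window, correct_baseline = TRUE,
                      clip_negative = FALSE, anchor_k = 1L) {
  stopifnot(inherits(spectrum, "ev_spectrum"))
  idx <- band_index(spectrum$wavenumber, window)
  if (length(idx) < 2L ||
      window$lo < min(spectrum$wavenumber) - 1e-9 ||
      window$hi > max(spectrum$wavenumber) + 1e-9) {
    stop("spectrum does not cover band ", window$name,
         " (", window$lo, "-", window$hi, " cm^-1)")
  }
  s <- if (correct_baseline) {
    subtract_linear_baseline(spectrum, window, anchor_k)
  } else {
    out <- spectrum
    out$wavenumber <- spectrum$wavenumber[idx]
    out$absorbance <- spectrum$absorbance[idx]
    out
  }
  a <- s$absorbance
  if (clip_negative) a <- pmax(a, 0)
  pracma::trapz(s$wavenumber, a)
}

#' Per-subject spectral feature table
#'
#' Computes, for every subject, the four integrated band areas plus the
#' lipid-to-protein ratio `lpr = area_2800_3000 / area_1470_1700` and the
#' lipid-to-nucleic-acid ratio `lnr = area_2800_3000 / area_1000_1200`.
#' Areas are taken on per-band baseline-corrected but *not* per-band
#' re-normalized spectra (per-band normalization would force every area to
#' one); comparability across subjects comes from the upstream full-spectrum
#' normalization stage. Ratio columns are `NA` (with a warning) when the
#' denominator area is zero.
#'
#' @param dataset An [ev_dataset()], already preprocessed at full-spectrum
#'   scope (see [preprocess_band()] with [full_range_band()]).
#' @param bands Named list of [band()] objects; default [ftir_bands()].
#' @param clip_negative Passed to [band_area()].
#' @return A [tibble::tibble()] with `subject_id`, `group`, one
#'   `area_<lo>_<hi>` column per band, `lpr`, `lnr`.
#' @export
build_feature_table <- function(dataset, bands = ftir_bands(),
                                clip_negative = FALSE) {
  stopifnot(inherits(dataset, "ev_dataset"))
  areas <- sapply(bands, function(b) {
    vapply(seq_len(n_subjects(dataset)), function(i) {
      band_area(get_spectrum(dataset, i), b, clip_negative = clip_negative)
    }, numeric(1))
  })
  areas <- matrix(areas, nrow = n_subjects(dataset),
                  dimnames = list(NULL, paste0("area_", vapply(bands, `[[`,
                                               character(1), "name"))))
  out <- tibble::tibble(subject_id = dataset$subject_id,
                        group = dataset$group)
  out <- tibble::add_column(out, !!!as.data.frame(areas))
  safe_ratio <- function(num, den, label) {
    bad <- den == 0
    if (any(bad)) warning("zero denominator area for ", label,
                          " in ", sum(bad), " subject(s); ratio set to NA")
    ifelse(bad, NA_real_, num / den)
  }
  if (all(c("area_2800_3000", "area_1470_1700") %in% names(out))) {
    out$lpr <- safe_ratio(out$area_2800_3000, out$area_1470_1700, "lpr")
  }
  if (all(c("area_2800_3000", "area_1000_1200") %in% names(out))) {
    out$lnr <- safe_ratio(out$area_2800_3000, out$area_1000_1200, "lnr")
  }
  out
}

#' Append PCA-LDA band-shape scores to a feature table
#'
#' Adds one `ld1_<lo>_<hi>` column per band, computed with
#' [pca_lda_scores()] on the band-shape (baseline-corrected,
#' area-normalized) slices.
#'
#' @param features Feature table from [build_feature_table()].
#' @param dataset The matching [ev_dataset()].
#' @param bands Bands to score (default the three shape-informative bands:
#'   amide, ester C=O, CH stretch).
#' @param n_components Number of principal components (default 2).
#' @return The feature table with LD1 columns appended.
#' @export
add_ld1_scores <- function(features, dataset,
                           bands = ftir_bands()[c("amide", "ester", "ch")],
                           n_components = 2L) {
  for (b in bands) {
    sc <- pca_lda_scores(dataset, b, n_components = n_components)
    features[[paste0("ld1_", b$name)]] <- sc[match(features$subject_id, names(sc))]
  }
  features
}
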