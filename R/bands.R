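#' Define a wavenumber band
#'
#' A band is a closed interval `[lo, hi]` on the wavenumber axis (cm^-1) used
#' for baseline subtraction, integration and band-shape analysis. A grid point
#' nu belongs to the band iff `lo <= nu <= hi`.
#'
#' @param name Short identifier, used to label derived feature columns.
#' @param lo,hi Band limits in cm^-1, `lo < hi`.
#' @return An object of class `band_definition`.
#' @examples
#' band("amide", 1470, 1700)
#' @export
band <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop("band limits must be finite with lo < hi (got ", lo, ", ", hi, ")")
  }
  structure(list(name = name, lo = lo, hi = hi), class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g cm^-1\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' Canonical mid-infrared analysis bands
#'
#' The four absorption windows analysed throughout the package:
#' carbohydrates and nucleic acids (1000-1200 cm^-1), protein amide I and II
#' (1470-1700 cm^-1), lipid-ester C=O stretching (1720-1760 cm^-1), and lipid
#' C-H stretching (2800-3000 cm^-1). The C=O window defaults to 1720-1760,
#' the interval used for all quantitative summaries; a narrower 1720-1740
#' variant is sometimes used for display and can be built with [band()].
#'
#' @return Named list of [band()] objects.
#' @export
ftir_bands <- function() {
  list(
    carbo = band("1000_1200", 1000, 1200),
    amide = band("1470_1700", 1470, 1700),
    ester = band("1720_1760", 1720, 1760),
    ch    = band("2800_3000", 2800, 3000)
  )
}

#' Full-spectrum normalization window
#'
#' Window used for the whole-spectrum preprocessing stage (full-range linear
#' baseline plus area normalization) before any per-band work.
#'
#' @return A [band()] spanning 900-3050 cm^-1.
#' @export
full_range_band <- function() band("full", 900, 3050)

# indices of grid points inside a closed band window
band_index <- function(wavenumber, window) {
  which(wavenumber >= window$lo & wavenumber <= window$hi)
}
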