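#' Read spectra from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`csv_wide`}{First column `wavenumber`, one numeric column per
#'     subject. Group labels live in a two-column manifest CSV
#'     (`subject_id,group`), by default `<path>_manifest.csv`, read
#'     automatically when present.}
#'   \item{`csv_long`}{Columns `subject_id`, `wavenumber`, `absorbance` and
#'     optionally `group`.}
#'   \item{`jcampdx`}{Minimal JCAMP-DX dialect: one spectrum per file,
#'     `##XYDATA=(X++(Y..Y))` tables with optional `XFACTOR`/`YFACTOR`.
#'     Read-only.}
#' }
#' Descending wavenumber axes (the native instrument order, 4000 down to
#' 650 cm^-1) are reversed on ingestion; storage is always ascending.
#' Missing labels yield a dataset with unknown groups, which group-wise
#' operations later refuse.
#'
#' @param path File path (for `jcampdx`, may be a vector of one-per-subject
#'   files).
#' @param format One of `"csv_wide"`, `"csv_long"`, `"jcampdx"`.
#' @param manifest Optional path to a `subject_id,group` CSV; defaults to
#'   `<path>_manifest.csv` for `csv_wide` if that file exists.
#' @return An [ev_dataset()].
#' @export
read_spectra <- function(path, format = c("csv_wide", "csv_long", "jcampdx"),
                         manifest = NULL) {
  format <- match.arg(format)
  switch(format,
    csv_wide = read_csv_wide(path, manifest),
    csv_long = read_csv_long(path),
    jcampdx  = bind_spectra(lapply(path, read_jcampdx_one))
  )
}

default_manifest_path <- function(path) sub("\\.csv$", "_manifest.csv", path)

read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(m))) {
    stop("manifest must have columns subject_id and group: ", path)
  }
  m
}

read_csv_wide <- function(path, manifest = NULL) {
  stopifnot(file.exists(path))
  x <- utils::read.csv(path, check.names = FALSE)
  if (ncol(x) < 2L) stop("csv_wide needs a wavenumber column plus >=1 subject")
  if (names(x)[1] != "wavenumber") {
    stop("csv_wide: first column must be named 'wavenumber' (got '",
         names(x)[1], "')")
  }
  wn <- x[[1]]
  if (!is.numeric(wn)) stop("wavenumber column must be numeric")
  a <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(a)) stop("ragged or non-numeric absorbance columns")
  ids <- names(x)[-1]
  group <- rep(NA_character_, length(ids))
  if (is.null(manifest)) {
    cand <- default_manifest_path(path)
    if (file.exists(cand)) manifest <- cand
  }
  if (!is.null(manifest)) {
    m <- read_manifest(manifest)
    group <- m$group[match(ids, m$subject_id)]
  }
  ev_dataset(wn, t(a), ids, group)
}

read_csv_long <- function(path) {
  stopifnot(file.exists(path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "wavenumber", "absorbance")
  if (!all(need %in% names(x))) {
    stop("csv_long needs columns ", paste(need, collapse = ", "))
  }
  if (!is.numeric(x$wavenumber)) stop("wavenumber column must be numeric")
  spectra <- lapply(split(x, x$subject_id), function(d) {
    g <- if ("group" %in% names(d)) d$group[1] else NA
    ev_spectrum(d$wavenumber, d$absorbance, d$subject_id[1], g)
  })
  # preserve file order of first appearance
  first <- vapply(split(seq_len(nrow(x)), x$subject_id), min, numeric(1))
  bind_spectra(spectra[order(first)])
}

# Minimal JCAMP-DX: ##XYDATA=(X++(Y..Y)); x of each line is the abscissa of
# its first ordinate, remaining ordinates advance by the grid step.
read_jcampdx_one <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  grab <- function(key, default = NA) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^##", key, "="), "", hit[1])
  }
  title   <- grab("TITLE", "jcamp")
  xfactor <- as.numeric(grab("XFACTOR", "1"))
  yfactor <- as.numeric(grab("YFACTOR", "1"))
  deltax  <- suppressWarnings(as.numeric(grab("DELTAX", NA)))
  start <- grep("^##XYDATA=\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  if (!length(start)) stop("no ##XYDATA=(X++(Y..Y)) table in ", path)
  stop_at <- grep("^##", lines)
  stop_at <- c(stop_at[stop_at > start[1]], length(lines) + 1L)[1]
  body <- lines[(start[1] + 1L):(stop_at - 1L)]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "[ \t]+")[[1]]))
  xs <- vapply(rows, `[`, numeric(1), 1L)
  ny <- vapply(rows, length, integer(1)) - 1L
  if (is.na(deltax)) {
    deltax <- if (length(xs) > 1L) (xs[2] - xs[1]) / ny[1] else 1
  }
  wn <- unlist(mapply(function(x0, n) x0 + deltax * (seq_len(n) - 1L),
                      xs, ny, SIMPLIFY = FALSE))
  ab <- unlist(lapply(rows, `[`, -1L))
  ev_spectrum(wn * xfactor, ab * yfactor,
              subject_id = title, group = NA)
}

#' Write spectra to disk
#'
#' Inverse of [read_spectra()] for the CSV dialects: a round trip through
#' disk reproduces the dataset to within 1e-12. For `csv_wide`, group labels
#' (when known) are written to a sidecar manifest `<path>_manifest.csv`.
#'
#' @param dataset A non-empty [ev_dataset()].
#' @param path Output file path.
#' @param format `"csv_wide"` or `"csv_long"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(dataset, path, format = c("csv_wide", "csv_long")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "ev_dataset"))
  if (n_subjects(dataset) == 0L) stop("refusing to write an empty dataset")
  if (format == "csv_wide") {
    out <- data.frame(wavenumber = dataset$wavenumber,
                      t(dataset$absorbance), check.names = FALSE)
    names(out) <- c("wavenumber", dataset$subject_id)
    utils::write.csv(format_numeric_df(out), path, row.names = FALSE, quote = FALSE)
    if (!anyNA(dataset$group)) {
      utils::write.csv(
        data.frame(subject_id = dataset$subject_id,
                   group = as.character(dataset$group)),
        default_manifest_path(path), row.names = FALSE, quote = FALSE)
    }
  } else {
    long <- data.frame(
      subject_id = rep(dataset$subject_id, each = length(dataset$wavenumber)),
      wavenumber = rep(dataset$wavenumber, times = n_subjects(dataset)),
      absorbance = as.vector(t(dataset$absorbance)),
      group = rep(as.character(dataset$group), each = length(dataset$wavenumber))
    )
    utils::write.csv(format_numeric_df(long), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# full-precision text so read(write(d)) == d to 1e-12
format_numeric_df <- function(d) {
  d[] <- lapply(d, function(col) {
    if (is.numeric(col)) formatC(col, digits = 17, format = "g") else col
  })
  d
}

#' Interpolate all spectra to one shared uniform grid
#'
#' Linearly interpolates every spectrum onto a uniform ascending grid with
#' the requested step, covering the intersection of all spectral ranges.
#' Datasets already on a shared grid pass through unchanged when the grid
#' matches. Linear interpolation is exact for piecewise-linear spectra; no
#' smoothing is applied.
#'
#' @param spectra List of [ev_spectrum()] objects or an [ev_dataset()].
#' @param step Grid step in cm^-1 (default 2).
#' @return An [ev_dataset()] on the common grid.
#' @export
common_grid <- function(spectra, step = 2) {
  if (inherits(spectra, "ev_dataset")) {
    spectra <- lapply(seq_len(n_subjects(spectra)),
                      function(i) get_spectrum(spectra, i))
  }
  lo <- max(vapply(spectra, function(s) min(s$wavenumber), numeric(1)))
  hi <- min(vapply(spectra, function(s) max(s$wavenumber), numeric(1)))
  if (lo >= hi) stop("spectra have no overlapping wavenumber range")
  grid <- seq(lo, hi, by = step)
  interp <- lapply(spectra, function(s) {
    a <- stats::approx(s$wavenumber, s$absorbance, xout = grid)$y
    ev_spectrum(grid, a, s$subject_id, as.character(s$group))
  })
  bind_spectra(interp)
}
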