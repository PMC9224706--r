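#' Construct a single spectrum
#'
#' The canonical in-memory representation of one subject's absorbance
#' spectrum. The wavenumber axis is always stored ascending in cm^-1;
#' descending input is reversed (together with the absorbance values).
#'
#' @param wavenumber Numeric vector, strictly monotonic, cm^-1.
#' @param absorbance Numeric vector of the same length, unitless.
#' @param subject_id Subject identifier (string).
#' @param group `"control"`, `"case"` or `NA` when unknown.
#' @return An object of class `ev_spectrum`.
#' @examples
#' s <- ev_spectrum(seq(650, 4000, 2), rnorm(1676), "S01", "control")
#' @export
ev_spectrum <- function(wavenumber, absorbance, subject_id = "S1", group = NA) {
  wavenumber <- as.numeric(wavenumber)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumber) != length(absorbance)) {
    stop("wavenumber and absorbance lengths differ (",
         length(wavenumber), " vs ", length(absorbance), ")")
  }
  d <- diff(wavenumber)
  if (any(d == 0)) {
    dup <- wavenumber[which(d == 0)[1]]
    stop("duplicated wavenumber value: ", format(dup))
  }
  if (all(d < 0)) {            # stored descending: normalize orientation
    wavenumber <- rev(wavenumber)
    absorbance <- rev(absorbance)
  } else if (any(d < 0)) {
    stop("wavenumber axis is not monotonic")
  }
  if (any(!is.finite(absorbance))) stop("non-finite absorbance values")
  group <- as_group(group)
  structure(
    list(wavenumber = wavenumber, absorbance = absorbance,
         subject_id = as.character(subject_id), group = group),
    class = "ev_spectrum"
  )
}

as_group <- function(group) {
  g <- factor(as.character(group), levels = c("control", "case"))
  bad <- !is.na(group) & is.na(g)
  if (any(bad)) {
    stop("group must be 'control' or 'case' (got ",
         paste(unique(as.character(group)[bad]), collapse = ", "), ")")
  }
  g
}

#' @export
print.ev_spectrum <- function(x, ...) {
  cat(sprintf("<ev_spectrum> %s [%s]: %d points, %g-%g cm^-1\n",
              x$subject_id, as.character(x$group), length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' Construct a spectral dataset
#'
#' A cohort of spectra on one shared wavenumber grid, stored as a
#' subjects-by-wavenumbers absorbance matrix plus a binary group label per
#' subject. All group-wise operations require at least one subject per group
#' and refuse datasets with unknown labels.
#'
#' @param wavenumber Shared ascending grid (cm^-1).
#' @param absorbance Numeric matrix, one row per subject.
#' @param subject_id Character vector of unique subject identifiers.
#' @param group Vector of `"control"`/`"case"` (or `NA`) per subject.
#' @return An object of class `ev_dataset`.
#' @export
ev_dataset <- function(wavenumber, absorbance, subject_id, group = NA) {
  wavenumber <- as.numeric(wavenumber)
  absorbance <- as.matrix(absorbance)
  if (ncol(absorbance) != length(wavenumber)) {
    stop("absorbance must have one column per wavenumber")
  }
  if (length(subject_id) != nrow(absorbance)) {
    stop("one subject_id per spectrum required")
  }
  if (anyDuplicated(subject_id)) stop("subject_id values must be unique")
  d <- diff(wavenumber)
  if (any(d == 0)) stop("duplicated wavenumber value: ",
                        format(wavenumber[which(d == 0)[1]]))
  if (all(d < 0)) {
    wavenumber <- rev(wavenumber)
    absorbance <- absorbance[, rev(seq_along(wavenumber)), drop = FALSE]
  } else if (any(d < 0)) stop("wavenumber axis is not monotonic")
  if (any(!is.finite(absorbance))) stop("non-finite absorbance values")
  if (length(group) == 1L) group <- rep(group, nrow(absorbance))
  group <- as_group(group)
  if (length(group) != nrow(absorbance)) stop("one group label per spectrum required")
  dimnames(absorbance) <- list(as.character(subject_id), NULL)
  structure(
    list(wavenumber = wavenumber, absorbance = absorbance,
         subject_id = as.character(subject_id), group = group),
    class = "ev_dataset"
  )
}

#' Assemble a dataset from a list of spectra
#'
#' @param spectra List of [ev_spectrum()] objects sharing an identical grid.
#' @return An [ev_dataset()].
#' @export
bind_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  grid <- spectra[[1]]$wavenumber
  for (s in spectra) {
    if (length(s$wavenumber) != length(grid) ||
        max(abs(s$wavenumber - grid)) > 1e-9) {
      stop("all spectra must share an identical wavenumber grid; ",
           "use common_grid() first")
    }
  }
  ev_dataset(
    wavenumber = grid,
    absorbance = do.call(rbind, lapply(spectra, `[[`, "absorbance")),
    subject_id = vapply(spectra, `[[`, character(1), "subject_id"),
    group      = vapply(spectra, function(s) as.character(s$group), character(1))
  )
}

#' Extract one subject's spectrum from a dataset
#'
#' @param dataset An [ev_dataset()].
#' @param i Row index or subject id.
#' @return An [ev_spectrum()].
#' @export
get_spectrum <- function(dataset, i) {
  stopifnot(inherits(dataset, "ev_dataset"))
  if (is.character(i)) i <- match(i, dataset$subject_id)
  ev_spectrum(dataset$wavenumber, dataset$absorbance[i, ],
              dataset$subject_id[i], as.character(dataset$group[i]))
}

#' Number of subjects in a dataset
#' @param dataset An [ev_dataset()].
#' @return Integer count.
#' @export
n_subjects <- function(dataset) nrow(dataset$absorbance)

#' @export
print.ev_dataset <- function(x, ...) {
  tab <- table(x$group, useNA = "ifany")
  cat(sprintf("<ev_dataset> %d subjects (%s), %d points, %g-%g cm^-1\n",
              n_subjects(x),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

# group-wise ops refuse unknown labels
check_groups <- function(dataset, min_per_group = 1L) {
  if (anyNA(dataset$group)) {
    stop("dataset has subjects with unknown group; attach labels first")
  }
  tab <- table(dataset$group)
  if (any(tab < min_per_group)) {
    stop("each group needs at least ", min_per_group, " subject(s); got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  invisible(TRUE)
}

#' Average replicate spectra per subject
#'
#' Utility for acquisitions with several replicate spectra per subject: rows
#' sharing a subject id are replaced by their pointwise mean. One spectrum per
#' subject is the default convention of the whole analysis chain.
#'
#' @param spectra List of [ev_spectrum()] objects (replicates share
#'   `subject_id`; grids must be identical).
#' @return An [ev_dataset()] with one row per distinct subject.
#' @export
replicate_mean <- function(spectra) {
  ids <- vapply(spectra, `[[`, character(1), "subject_id")
  merged <- lapply(unique(ids), function(id) {
    reps <- spectra[ids == id]
    a <- colMeans(do.call(rbind, lapply(reps, `[[`, "absorbance")))
    ev_spectrum(reps[[1]]$wavenumber, a, id, as.character(reps[[1]]$group))
  })
  bind_spectra(merged)
}
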