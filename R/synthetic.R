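#' Gaussian peak specification for the spectral generator
#'
#' One mid-IR absorption peak, with optional group effects applied to the
#' case group only: a multiplicative amplitude ratio (`group_scale`) and a
#' center shift in cm^-1 (`group_shift`).
#'
#' @param center Peak center, cm^-1.
#' @param amplitude Peak height, absorbance units, >= 0.
#' @param width Gaussian standard deviation, cm^-1, > 0.
#' @param group_scale Case/control amplitude ratio (1 = no effect).
#' @param group_shift Case center shift, cm^-1 (0 = no effect).
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(center, amplitude, width, group_scale = 1,
                      group_shift = 0) {
  stopifnot(amplitude >= 0, width > 0)
  structure(list(center = center, amplitude = amplitude, width = width,
                 group_scale = group_scale, group_shift = group_shift),
            class = "peak_spec")
}

#' Default mid-IR peak set for an EV-enriched serum film
#'
#' Gaussian components at the canonical band positions of a dried
#' EV-enriched film: carbohydrate/nucleic-acid backbone modes (1045, 1080,
#' 1160 cm^-1), protein amide II and I (1545, 1655 cm^-1), the lipid-ester
#' C=O stretch (1735 cm^-1), the lipid CH2/CH3 stretches (2850, 2920,
#' 2960 cm^-1), and the broad amide A / O-H envelope near 3300 cm^-1.
#' Relative amplitudes are chosen to resemble a protein-dominated EV film
#' (amide I the strongest feature, weak ester peak). Group effects default
#' to zero; [cohort_spec()] presets plant them.
#'
#' @return List of [peak_spec()] objects.
#' @export
default_ev_peaks <- function() {
  list(
    carbo_1045 = peak_spec(1045, 0.28, 25),
    carbo_1080 = peak_spec(1080, 0.30, 22),
    carbo_1160 = peak_spec(1160, 0.18, 20),
    amide_II   = peak_spec(1545, 0.55, 22),
    amide_I    = peak_spec(1655, 1.00, 25),
    ester_CO   = peak_spec(1735, 0.06, 12),
    ch2_sym    = peak_spec(2850, 0.12, 12),
    ch2_asym   = peak_spec(2920, 0.22, 14),
    ch3_asym   = peak_spec(2960, 0.10, 12),
    amide_A    = peak_spec(3300, 0.35, 80)
  )
}

#' Spectral cohort specification
#'
#' Study conditions for the synthetic spectral generator. Defaults mirror the
#' reference two-group design: 19 controls and 20 cases on a 650-4000 cm^-1
#' grid at 2 cm^-1 (1676 points), additive white Gaussian absorbance noise
#' (sd 0.002), a random linear baseline drift (slope drawn uniformly from
#' +/- 2e-5 absorbance per cm^-1), and lognormal between-subject per-peak
#' amplitude variation with coefficient of variation 0.08.
#'
#' @param n_control,n_case Subjects per group.
#' @param peaks List of [peak_spec()]s (default [default_ev_peaks()]).
#' @param noise_sd Absorbance noise standard deviation, >= 0.
#' @param drift_range Length-2 range of baseline slopes (absorbance/cm^-1).
#' @param amplitude_cv Between-subject per-peak amplitude CV, >= 0.
#' @param wn_min,wn_max,step Wavenumber grid, cm^-1.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 19L, n_case = 20L,
                        peaks = default_ev_peaks(),
                        noise_sd = 0.002, drift_range = c(-2e-5, 2e-5),
                        amplitude_cv = 0.08,
                        wn_min = 650, wn_max = 4000, step = 2) {
  stopifnot(n_control >= 1L, n_case >= 1L, noise_sd >= 0, amplitude_cv >= 0,
            length(drift_range) == 2L, wn_min < wn_max, step > 0)
  stopifnot(all(vapply(peaks, inherits, logical(1), "peak_spec")))
  structure(
    list(n_control = as.integer(n_control), n_case = as.integer(n_case),
         peaks = peaks, noise_sd = noise_sd,
         drift_range = sort(as.numeric(drift_range)),
         amplitude_cv = amplitude_cv,
         wavenumber = seq(wn_min, wn_max, by = step)),
    class = "cohort_spec"
  )
}

#' Plant a lipid-intensity and amide-shape group effect
#'
#' Convenience modifier for effect-recovery studies: scales the case-group
#' CH-stretch amplitudes by `1 + d * amplitude_cv` (so the induced
#' standardized between-group difference in the CH band area is
#' approximately `d`) and shifts the case-group amide I center by
#' `amide_shift` cm^-1 (a pure band-shape effect targeted by the PCA-LDA
#' score).
#'
#' @param spec A [cohort_spec()].
#' @param d Standardized effect size on the CH-stretch band area.
#' @param amide_shift Case amide I center shift, cm^-1.
#' @return The modified `cohort_spec`.
#' @export
plant_group_effect <- function(spec, d = 3, amide_shift = 5) {
  stopifnot(inherits(spec, "cohort_spec"))
  scale <- 1 + d * spec$amplitude_cv
  for (nm in c("ch2_sym", "ch2_asym", "ch3_asym")) {
    if (!is.null(spec$peaks[[nm]])) spec$peaks[[nm]]$group_scale <- scale
  }
  if (!is.null(spec$peaks$amide_I)) spec$peaks$amide_I$group_shift <- amide_shift
  spec
}

#' Generate one synthetic spectrum
#'
#' Absorbance = sum of Gaussian peaks (case group: amplitudes multiplied by
#' `group_scale`, centers shifted by `group_shift`) with lognormal
#' between-subject amplitude variation, plus a linear baseline drift with a
#' uniformly drawn slope, plus i.i.d. Gaussian noise. Uses the current RNG
#' state: seed the session (or use [generate_cohort()]'s `seed`) for
#' reproducibility.
#'
#' @param spec A [cohort_spec()].
#' @param group `"control"` or `"case"`.
#' @param subject_id Identifier for the generated subject.
#' @return An [ev_spectrum()].
#' @export
generate_spectrum <- function(spec, group = c("control", "case"),
                              subject_id = "S1") {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  wn <- spec$wavenumber
  a <- numeric(length(wn))
  cv <- spec$amplitude_cv
  sdlog <- sqrt(log(1 + cv^2))
  for (p in spec$peaks) {
    amp <- p$amplitude
    ctr <- p$center
    if (group == "case") {
      amp <- amp * p$group_scale
      ctr <- ctr + p$group_shift
    }
    if (cv > 0) amp <- amp * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    a <- a + amp * exp(-(wn - ctr)^2 / (2 * p$width^2))
  }
  slope <- stats::runif(1, spec$drift_range[1], spec$drift_range[2])
  a <- a + slope * (wn - wn[1])
  if (spec$noise_sd > 0) a <- a + stats::rnorm(length(wn), 0, spec$noise_sd)
  ev_spectrum(wn, a, subject_id, group)
}

#' Generate a labeled spectral cohort
#'
#' `n_control + n_case` spectra from [generate_spectrum()], labeled and
#' bound into a dataset. Deterministic given `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return An [ev_dataset()].
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  groups <- c(rep("control", spec$n_control), rep("case", spec$n_case))
  ids <- sprintf("%s%02d",
                 ifelse(groups == "control", "C", "H"),
                 c(seq_len(spec$n_control), seq_len(spec$n_case)))
  bind_spectra(lapply(seq_along(groups), function(i) {
    generate_spectrum(spec, groups[i], ids[i])
  }))
}

#' Reference marker distribution parameters
#'
#' Group means and standard deviations of the seven spectral markers (four
#' integrated band areas, three PCA-LDA LD1 band-shape scores) reported for
#' the reference 19-control / 20-case HCC study that defines this package's
#' study conditions, optionally with the two conventional circulating HCC
#' markers (PIVKA-II, mAU/mL; AFP, ng/mL) measured on the same subjects.
#'
#' @param include_clinical Append the PIVKA-II and AFP rows.
#' @return A [tibble::tibble()] with columns `marker`, `mean_control`,
#'   `sd_control`, `mean_case`, `sd_case`.
#' @export
reference_marker_params <- function(include_clinical = FALSE) {
  m <- tibble::tribble(
    ~marker,          ~mean_control, ~sd_control, ~mean_case, ~sd_case,
    "area_1470_1700",         12.0,         3.1,        9.7,      3.6,
    "area_1000_1200",         4.16,        1.22,       3.32,     0.99,
    "area_2800_3000",        0.023,       0.006,      0.030,    0.008,
    "area_1720_1760",       0.0012,      0.0007,     0.0017,   0.0008,
    "ld1_1470_1700",         -0.54,        0.77,       0.52,     1.18,
    "ld1_2800_3000",         -0.48,        1.24,       0.46,     0.70,
    "ld1_1720_1760",         -0.77,        1.10,       0.73,     0.90
  )
  if (include_clinical) {
    m <- rbind(m, tibble::tribble(
      ~marker,  ~mean_control, ~sd_control, ~mean_case, ~sd_case,
      "pivka",             14,           4,       3205,     9987,
      "afp",                2,           1,        193,      417
    ))
  }
  m
}

#' Feature-cohort specification
#'
#' Marker-level study conditions: independent Gaussian markers per subject,
#' with per-group means and SDs defaulting to the reference cohort
#' parameters of [reference_marker_params()] and group sizes 19/20. The
#' independence of markers is a documented simplification: no between-marker
#' covariances are modeled.
#'
#' @param markers Parameter table with columns `marker`, `mean_control`,
#'   `sd_control`, `mean_case`, `sd_case` (all SDs > 0).
#' @param n_control,n_case Subjects per group.
#' @return An object of class `feature_cohort_spec`.
#' @export
feature_cohort_spec <- function(markers = reference_marker_params(),
                                n_control = 19L, n_case = 20L) {
  markers <- tibble::as_tibble(markers)
  need <- c("marker", "mean_control", "sd_control", "mean_case", "sd_case")
  stopifnot(all(need %in% names(markers)),
            all(markers$sd_control > 0), all(markers$sd_case > 0),
            n_control >= 1L, n_case >= 1L)
  structure(list(markers = markers, n_control = as.integer(n_control),
                 n_case = as.integer(n_case)),
            class = "feature_cohort_spec")
}

#' Generate a marker-level cohort
#'
#' Independent Gaussian draws per marker per subject with the configured
#' group means/SDs. Deterministic given `seed`.
#'
#' @param spec A [feature_cohort_spec()].
#' @param seed Optional integer seed.
#' @return A feature table: `subject_id`, `group`, one column per marker.
#' @export
generate_feature_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "feature_cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n0 <- spec$n_control; n1 <- spec$n_case
  groups <- c(rep("control", n0), rep("case", n1))
  out <- tibble::tibble(
    subject_id = sprintf("%s%02d", ifelse(groups == "control", "C", "H"),
                         c(seq_len(n0), seq_len(n1))),
    group = as_group(groups)
  )
  for (i in seq_len(nrow(spec$markers))) {
    p <- spec$markers[i, ]
    out[[p$marker]] <- c(stats::rnorm(n0, p$mean_control, p$sd_control),
                         stats::rnorm(n1, p$mean_case, p$sd_case))
  }
  out
}

#' Binormal AUC implied by marker parameters
#'
#' For a Gaussian marker with group means `mu0`, `mu1` and SDs `s0`, `s1`,
#' the population AUC is `pnorm(|mu1 - mu0| / sqrt(s0^2 + s1^2))`. Used as
#' the internal oracle for replicate-averaged empirical AUCs.
#'
#' @param params Parameter table as in [reference_marker_params()].
#' @return Named numeric vector of AUCs.
#' @export
binormal_auc <- function(params) {
  stats::setNames(
    stats::pnorm(abs(params$mean_case - params$mean_control) /
                   sqrt(params$sd_control^2 + params$sd_case^2)),
    params$marker
  )
}
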