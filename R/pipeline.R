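#' Group summary and Wilcoxon test per marker
#'
#' One row per marker: group means and SDs plus the two-sided Wilcoxon
#' rank-sum p-value. Raw p-values are reported; an optional
#' Benjamini-Hochberg adjusted column can be appended.
#'
#' @param features Feature table (`group` column plus numeric markers).
#' @param markers Optional character vector selecting marker columns.
#' @param adjust Append a `p_adjusted` (Benjamini-Hochberg) column.
#' @return A [tibble::tibble()].
#' @export
marker_summary <- function(features, markers = NULL, adjust = FALSE) {
  x <- marker_frame(features, markers)
  g <- as_group(features$group)
  out <- tibble::tibble(
    marker = names(x),
    mean_control = vapply(x, function(v) mean(v[g == "control"]), numeric(1)),
    sd_control   = vapply(x, function(v) stats::sd(v[g == "control"]), numeric(1)),
    mean_case    = vapply(x, function(v) mean(v[g == "case"]), numeric(1)),
    sd_case      = vapply(x, function(v) stats::sd(v[g == "case"]), numeric(1)),
    p_value      = vapply(x, function(v) {
      wilcoxon_rank_sum(v[g == "control"], v[g == "case"])$p_value
    }, numeric(1))
  )
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}

#' ROC/AUC evaluation of every marker
#'
#' One oriented ROC per marker (markers on which controls score higher are
#' negated so every reported AUC is >= 0.5; the applied direction is
#' recorded), with DeLong or bootstrap confidence intervals and the Youden
#' operating point.
#'
#' @param features Feature table.
#' @param markers Optional character vector selecting marker columns.
#' @param ci_method Passed to [roc_auc()].
#' @return A [tibble::tibble()] with columns `marker`, `auc`, `ci_low`,
#'   `ci_high`, `direction`, `youden_sens`, `youden_spec`.
#' @export
evaluate_markers <- function(features, markers = NULL, ci_method = "delong") {
  x <- marker_frame(features, markers)
  g <- as_group(features$group)
  rows <- lapply(names(x), function(nm) {
    roc <- roc_auc(x[[nm]], g, ci_method = ci_method, orient = TRUE)
    yj <- youden_threshold(roc)
    tibble::tibble(marker = nm, auc = roc$auc, ci_low = roc$ci_low,
                   ci_high = roc$ci_high, direction = roc$direction,
                   youden_sens = yj$sensitivity, youden_spec = yj$specificity)
  })
  do.call(rbind, rows)
}

#' Assemble a pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. May be built directly or
#' loaded from YAML ([read_pipeline_config()]). Every field is checked
#' before any computation runs.
#'
#' @param source `"spectral"` (simulate a spectral cohort and run the full
#'   chain), `"features"` (simulate a marker-level cohort, statistics only),
#'   or `"csv"` (read spectra from `path`).
#' @param seed Integer seed; the whole pipeline is deterministic given the
#'   configuration and seed.
#' @param bands Named list of `c(lo, hi)` pairs or [band()] objects.
#' @param shape_bands Names of bands scored with PCA-LDA.
#' @param full_range `c(lo, hi)` full-spectrum normalization window.
#' @param n_components Principal components for PCA-LDA.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param stepwise Run stepwise marker combination.
#' @param effect_d,amide_shift Planted group effect for `source="spectral"`
#'   (0 = null cohort); see [plant_group_effect()].
#' @param n_control,n_case Group sizes for simulated sources.
#' @param path,format,manifest Input location for `source = "csv"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(source = c("spectral", "features", "csv"),
                            seed = 1L,
                            bands = NULL,
                            shape_bands = NULL,
                            full_range = c(900, 3050),
                            n_components = 2L,
                            ci_method = c("delong", "bootstrap"),
                            stepwise = TRUE,
                            effect_d = 0, amide_shift = 0,
                            n_control = 19L, n_case = 20L,
                            path = NULL, format = "csv_wide",
                            manifest = NULL) {
  source <- match.arg(source)
  ci_method <- match.arg(ci_method)
  if (is.null(bands)) {
    bands <- ftir_bands()
  } else {
    bands <- lapply(seq_along(bands), function(i) {
      b <- bands[[i]]
      if (inherits(b, "band_definition")) b
      else band(names(bands)[i], b[1], b[2])
    })
    names(bands) <- vapply(bands, `[[`, character(1), "name")
  }
  band_names <- vapply(bands, `[[`, character(1), "name")
  if (is.null(shape_bands)) {
    # default: the three shape-informative windows when present, else all
    shape_bands <- intersect(c("1470_1700", "1720_1760", "2800_3000"),
                             band_names)
    if (!length(shape_bands)) shape_bands <- band_names
  }
  unknown <- setdiff(shape_bands, band_names)
  if (length(unknown)) {
    stop("unknown shape band(s): ", paste(unknown, collapse = ", "),
         " (configured bands: ", paste(band_names, collapse = ", "), ")")
  }
  stopifnot(length(full_range) == 2L, full_range[1] < full_range[2],
            n_components >= 1L, is.numeric(seed), length(seed) == 1L,
            n_control >= 1L, n_case >= 1L, effect_d >= 0)
  if (source == "csv" && (is.null(path) || !file.exists(path))) {
    stop("source = 'csv' requires an existing input path")
  }
  structure(
    list(source = source, seed = as.integer(seed), bands = bands,
         shape_bands = shape_bands, full_range = as.numeric(full_range),
         n_components = as.integer(n_components), ci_method = ci_method,
         stepwise = isTRUE(stepwise), effect_d = effect_d,
         amide_shift = amide_shift, n_control = as.integer(n_control),
         n_case = as.integer(n_case), path = path, format = format,
         manifest = manifest),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the [pipeline_config()] arguments
#' (band entries as `name: [lo, hi]`) and validates it.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, y)
}

#' Run the end-to-end analysis
#'
#' Executes input acquisition (simulation or file), full-spectrum
#' preprocessing, band-feature extraction, PCA-LDA band-shape scoring with
#' LOOCV, and biomarker statistics (group summaries with Wilcoxon tests,
#' per-marker ROC/AUC with confidence intervals, stepwise logistic
#' combination with Youden and closest-top-left operating points). Identical
#' configuration and seed give identical reports.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress to stderr.
#' @return An object of class `analysis_report`: `summary` (group summary +
#'   Wilcoxon p per marker), `auc` (per-marker AUC table incl. the combined
#'   model when `stepwise`), `loocv` (per shape band), `stepwise_model`,
#'   `operating_points`, `features`, and the resolved `config`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[evftir] ", sprintf(...))
  set.seed(config$seed)
  t0 <- Sys.time()

  say("stage input (%s)", config$source)
  loocv <- list()
  if (config$source == "features") {
    features <- generate_feature_cohort(
      feature_cohort_spec(n_control = config$n_control,
                          n_case = config$n_case))
  } else {
    dataset <- if (config$source == "spectral") {
      spec <- cohort_spec(n_control = config$n_control,
                          n_case = config$n_case)
      if (config$effect_d > 0 || config$amide_shift != 0) {
        spec <- plant_group_effect(spec, d = config$effect_d,
                                   amide_shift = config$amide_shift)
      }
      generate_cohort(spec)
    } else {
      read_spectra(config$path, config$format, manifest = config$manifest)
    }
    say("stage preprocess (full range %g-%g)", config$full_range[1],
        config$full_range[2])
    full <- band("full", config$full_range[1], config$full_range[2])
    pre <- preprocess_band(dataset, full, normalize_after = TRUE)

    say("stage band features")
    features <- build_feature_table(pre, config$bands)
    shape <- config$bands[
      vapply(config$bands, `[[`, character(1), "name") %in% config$shape_bands]
    features <- add_ld1_scores(features, pre, bands = shape,
                               n_components = config$n_components)
    say("stage LOOCV")
    loocv <- lapply(shape, function(b) {
      loocv_classify(pre, b, n_components = config$n_components)
    })
    names(loocv) <- vapply(shape, `[[`, character(1), "name")
  }

  say("stage statistics")
  summary_tab <- marker_summary(features)
  auc_tab <- evaluate_markers(features, ci_method = config$ci_method)

  stepwise_model <- NULL
  operating <- NULL
  if (config$stepwise && ncol(marker_frame(features)) >= 2L) {
    say("stage stepwise combination")
    stepwise_model <- stepwise_select(features, features$group)
    croc <- combined_marker_roc(stepwise_model, features, features$group,
                                ci_method = config$ci_method)
    yj <- youden_threshold(croc)
    tl <- closest_topleft_threshold(croc)
    auc_tab <- rbind(auc_tab, tibble::tibble(
      marker = "stepwise", auc = croc$auc, ci_low = croc$ci_low,
      ci_high = croc$ci_high, direction = 1,
      youden_sens = yj$sensitivity, youden_spec = yj$specificity))
    operating <- list(youden = yj, closest_topleft = tl, roc = croc)
  }

  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  structure(
    list(summary = summary_tab, auc = auc_tab, loocv = loocv,
         stepwise_model = stepwise_model, operating_points = operating,
         features = features, config = config),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n-- group summary --\n")
  print(as.data.frame(x$summary), digits = 3)
  cat("-- AUC table --\n")
  print(as.data.frame(x$auc), digits = 3)
  if (length(x$loocv)) {
    cat("-- LOOCV --\n")
    for (cv in x$loocv) print(cv)
  }
  if (!is.null(x$stepwise_model)) {
    cat("-- stepwise model --\n")
    print(x$stepwise_model)
  }
  invisible(x)
}

#' Write report tables and JSON
#'
#' Emits `summary.csv` (group summary layout), `auc.csv` (AUC table with one
#' row per marker plus a `stepwise` row), `roc_<marker>.csv` coordinate
#' files for the combined model, `loocv.csv`, and `report.json` (the whole
#' report including the resolved configuration, sufficient to re-run
#' bit-identically).
#'
#' @param report An [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
make_report_tables <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(d, f) {
    p <- file.path(dir, f)
    utils::write.csv(d, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$summary, "summary.csv")
  wr(report$auc, "auc.csv")
  if (length(report$loocv)) {
    wr(do.call(rbind, lapply(report$loocv, function(cv) {
      data.frame(band = cv$band, n_folds = cv$n_folds, tp = cv$tp, fp = cv$fp,
                 tn = cv$tn, fn = cv$fn, sensitivity = cv$sensitivity,
                 specificity = cv$specificity, accuracy = cv$accuracy)
    })), "loocv.csv")
  }
  if (!is.null(report$operating_points)) {
    roc <- report$operating_points$roc
    wr(data.frame(threshold = roc$thresholds, sensitivity = roc$sensitivity,
                  specificity = roc$specificity), "roc_stepwise.csv")
  }
  json <- list(
    config = unclass_config(report$config),
    summary = report$summary,
    auc = report$auc,
    loocv = lapply(report$loocv, function(cv) {
      cv[c("band", "n_folds", "tp", "fp", "tn", "fn",
           "sensitivity", "specificity", "accuracy")]
    }),
    stepwise = if (!is.null(report$stepwise_model)) list(
      markers = report$stepwise_model$markers,
      coefficients = as.list(report$stepwise_model$coefficients),
      aic = report$stepwise_model$aic,
      converged = report$stepwise_model$converged
    ),
    operating_points = if (!is.null(report$operating_points)) list(
      youden = report$operating_points$youden,
      closest_topleft = report$operating_points$closest_topleft
    )
  )
  p <- file.path(dir, "report.json")
  jsonlite::write_json(json, p, auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, p)
  invisible(paths)
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$bands <- lapply(out$bands, function(b) c(b$lo, b$hi))
  out
}
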