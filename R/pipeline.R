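#' Run the full heat-stress analysis
#'
#' End-to-end orchestration: feature extraction over a cohort, the
#' Mann-Whitney/Holm separability screen, the four-classifier leave-one-out
#' report, the combined-feature (aa energy + RMSSD) classifier, and the
#' OA-based feature ranking. Deterministic for a given cohort; when a
#' configuration is supplied instead of a cohort, the cohort is generated
#' from the configuration seed first.
#'
#' @param cohort Cohort tibble (from [generate_cohort()] or
#'   [read_cohort()]), or `NULL` to generate one from `config`.
#' @param config A [cohort_config()], used when `cohort` is `NULL`.
#' @param alpha Significance level of the screen.
#' @param test `"unpaired"` or `"paired"` screen variant.
#' @param classifiers Classifiers for the per-feature report.
#' @param pair Two feature columns for the combined classifier.
#' @param low,high,order Filter design.
#' @param rmssd_method Passed to [rmssd()].
#' @param out_dir Optional output directory; when given, all result tables
#'   are written as CSV plus a JSON summary and a run log.
#' @return An object of class `heat_analysis`: list with `features`,
#'   `screen`, `classification`, `combined`, `ranking`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 6, seed = 1))
#' res <- run_heat_stress_analysis(cohort, classifiers = "lda")
#' res$ranking
run_heat_stress_analysis <- function(cohort = NULL, config = NULL,
                                     alpha = 0.05,
                                     test = c("unpaired", "paired"),
                                     classifiers = c("mahalanobis", "lda", "qda", "svm"),
                                     pair = c("energy_aa_ppg", "rmssd"),
                                     low = 0.5, high = 7, order = 2,
                                     rmssd_method = "diff",
                                     out_dir = NULL) {
  test <- match.arg(test)
  if (is.null(cohort)) {
    if (is.null(config)) stop("supply either `cohort` or `config`", call. = FALSE)
    cohort <- generate_cohort(config)
  }
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  note("records: %d (%d subjects x %d stages)", nrow(cohort),
       length(unique(cohort$subject_id)), length(unique(cohort$stage)))
  note("filter: Butterworth order %d, %.3g-%.3g Hz, zero-phase", order, low, high)

  features <- withCallingHandlers(
    extract_cohort_features(cohort, low = low, high = high, order = order,
                            rmssd_method = rmssd_method),
    warning = function(w) {
      note("warning [features]: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  screen <- screen_features(features, alpha = alpha, test = test)
  note("screen: %d tests (%s), %d Holm-significant at alpha = %g",
       attr(screen, "n_tests"), test, sum(as.matrix(screen[, grep("^sig_", names(screen))])),
       alpha)
  classification <- classify_features(features, classifiers = classifiers)
  combined <- classify_feature_pair(features, pair)
  ranking <- rank_features(classification)
  note("best feature: %s (OA = %.2f%%)", ranking$feature[1], ranking$oa[1])

  res <- structure(
    list(features = features, screen = screen, classification = classification,
         combined = combined, ranking = ranking, log = log_lines,
         settings = list(alpha = alpha, test = test, classifiers = classifiers,
                         pair = pair, band = c(low, high), order = order,
                         rmssd_method = rmssd_method)),
    class = "heat_analysis"
  )
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

#' @export
print.heat_analysis <- function(x, ...) {
  cat("<heat_analysis>\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Write analysis results to disk
#'
#' Emits the feature matrix, the screen table, the classification cells and
#' OA table, and the combined-pair report as CSV, plus a JSON summary and a
#' plain-text run log.
#'
#' @param analysis A [run_heat_stress_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "heat_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(analysis$features, file.path(dir, "features.csv"))
  readr::write_csv(as.data.frame(analysis$screen), file.path(dir, "stat_table.csv"))
  readr::write_csv(analysis$classification$cells, file.path(dir, "classification_cells.csv"))
  readr::write_csv(analysis$classification$oa, file.path(dir, "classification_oa.csv"))
  readr::write_csv(analysis$combined, file.path(dir, "combined_pair.csv"))
  summary <- list(
    settings = analysis$settings,
    n_records = nrow(analysis$features),
    n_tests = attr(analysis$screen, "n_tests"),
    n_holm_significant = sum(as.matrix(
      analysis$screen[, grep("^sig_", names(analysis$screen))])),
    ranking = analysis$ranking,
    combined = analysis$combined[, c("comparison", "se", "pp", "f1")]
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(analysis$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
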