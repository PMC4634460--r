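#' Two-sample Mann-Whitney U test
#'
#' Wilcoxon rank-sum (Mann-Whitney U) test of two independent samples,
#' two-sided. The exact permutation distribution is used when the combined
#' sample size is at most 20 and there are no ties; otherwise the normal
#' approximation with mid-rank tie correction and continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `statistic` (the U statistic for `x`), `p_value`, and
#'   `exact` (whether the exact distribution was used).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
mann_whitney <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty", call. = FALSE)
  exact <- (length(x) + length(y) <= 20L) && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, exact = exact)
}

#' Wilcoxon signed-rank test of paired differences
#'
#' Paired-rank analogue used for within-subject comparisons (e.g. of aa
#' intervals before vs after exercise). Zero differences are dropped; if all
#' differences are zero the test is vacuous and p = 1 is returned with a
#' warning. Exact for at most 15 nonzero differences without tied
#' magnitudes, otherwise the corrected normal approximation.
#'
#' @param diffs Numeric vector of paired differences.
#' @return List with `statistic` (V, the positive-rank sum), `p_value`, and
#'   `exact`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))$p_value  # exact: 0.25
wilcoxon_signed_rank <- function(diffs) {
  if (length(diffs) < 1L) stop("need at least one difference", call. = FALSE)
  d <- diffs[diffs != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    return(list(statistic = 0, p_value = 1, exact = TRUE))
  }
  exact <- length(d) <= 15L && !anyDuplicated(abs(d))
  ht <- suppressWarnings(wilcox.test(d, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, exact = exact)
}

#' Holm-Bonferroni step-down rejection flags
#'
#' Step-down multiple-testing correction controlling the family-wise error
#' rate: p-values are sorted ascending and compared with
#' `alpha / (m - i + 1)`, stopping at the first failure. Uniformly more
#' powerful than the plain Bonferroni correction -- its rejections are
#' always a superset of Bonferroni's at the same level.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise significance level.
#' @return Logical vector of rejection flags, in input order.
#' @export
#' @examples
#' holm_bonferroni(c(0.001, 0.01, 0.02, 0.04))  # all TRUE
holm_bonferroni <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0L) return(logical(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE) || anyNA(pvals)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "holm") <= alpha
}

#' Separability screen over the 14 features
#'
#' For every feature, tests the baseline stage against each post-exercise
#' stage (BE vs E1, E2, E3) -- 42 tests in total -- and applies the
#' Holm-Bonferroni correction jointly over all of them. Reports raw
#' p-values, corrected significance flags, per-stage mean and SD, and each
#' feature's mean raw p-value across the three comparisons.
#'
#' The default uses the unpaired Mann-Whitney U test; `test = "paired"`
#' switches to the Wilcoxon signed-rank on within-subject differences for
#' sensitivity analysis.
#'
#' @param features Feature tibble from [extract_cohort_features()].
#' @param alpha Family-wise significance level.
#' @param test `"unpaired"` (Mann-Whitney) or `"paired"` (signed-rank).
#' @param feature_cols Feature columns to screen; defaults to the 14 of
#'   [ppg_feature_names()].
#' @return A tibble of class `heat_screen`, one row per feature, with
#'   columns `feature`, `mean_<stage>`, `sd_<stage>`, `p_<stage>`,
#'   `sig_<stage>` (Holm flags) and `p_mean`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 8, seed = 2))
#' screen_features(extract_cohort_features(cohort))
screen_features <- function(features, alpha = 0.05,
                            test = c("unpaired", "paired"),
                            feature_cols = ppg_feature_names()) {
  test <- match.arg(test)
  stopifnot(all(c("subject_id", "stage") %in% names(features)))
  missing_cols <- setdiff(feature_cols, names(features))
  if (length(missing_cols)) {
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stages <- levels(factor(features$stage))
  if (!"BE" %in% stages) stop("baseline stage 'BE' is missing", call. = FALSE)
  ex_stages <- setdiff(stages, "BE")
  for (st in stages) {
    if (sum(features$stage == st) < 2L) {
      stop(sprintf("stage %s has fewer than 2 records", st), call. = FALSE)
    }
  }
  be <- features[features$stage == "BE", ]
  pmat <- matrix(NA_real_, nrow = length(feature_cols), ncol = length(ex_stages),
                 dimnames = list(feature_cols, ex_stages))
  for (f in feature_cols) {
    for (st in ex_stages) {
      ex <- features[features$stage == st, ]
      if (test == "paired") {
        common <- intersect(be$subject_id, ex$subject_id)
        d <- ex[[f]][match(common, ex$subject_id)] - be[[f]][match(common, be$subject_id)]
        pmat[f, st] <- wilcoxon_signed_rank(d)$p_value
      } else {
        pmat[f, st] <- mann_whitney(be[[f]], ex[[f]])$p_value
      }
    }
  }
  sig <- matrix(holm_bonferroni(as.vector(pmat), alpha), nrow = nrow(pmat),
                dimnames = dimnames(pmat))
  out <- tibble::tibble(feature = feature_cols)
  for (st in stages) {
    vals <- features[features$stage == st, feature_cols, drop = FALSE]
    out[[paste0("mean_", tolower(st))]] <- unname(vapply(vals, mean, numeric(1)))
    out[[paste0("sd_", tolower(st))]] <- unname(vapply(vals, sd, numeric(1)))
  }
  for (st in ex_stages) out[[paste0("p_", tolower(st))]] <- unname(pmat[, st])
  for (st in ex_stages) out[[paste0("sig_", tolower(st))]] <- unname(sig[, st])
  out$p_mean <- unname(rowMeans(pmat))
  structure(out, class = c("heat_screen", class(out)),
            alpha = alpha, test = test, n_tests = length(pmat))
}

#' @export
tidy.heat_screen <- function(x, ...) {
  pcols <- grep("^p_(?!mean)", names(x), value = TRUE, perl = TRUE)
  long <- tidyr::pivot_longer(
    x[, c("feature", pcols, sub("^p_", "sig_", pcols))],
    cols = -"feature",
    names_to = c(".value", "comparison"),
    names_pattern = "(p|sig)_(.+)"
  )
  dplyr::rename(long, p_value = "p", significant = "sig") |>
    dplyr::mutate(comparison = toupper(.data$comparison))
}

#' @export
glance.heat_screen <- function(x, ...) {
  sig <- as.matrix(x[, grep("^sig_", names(x)), drop = FALSE])
  tibble::tibble(
    n_features = nrow(x),
    n_tests = attr(x, "n_tests"),
    n_significant = sum(sig),
    alpha = attr(x, "alpha"),
    test = attr(x, "test")
  )
}
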