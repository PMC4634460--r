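as_matrix_x <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  x
}

# Both classes must be present in every training fold; leave-one-out on a
# minimal dataset can legitimately reduce one class to a single point, which
# the per-class-covariance classifiers handle by pooling (see below).
check_train <- function(train_x, train_y) {
  train_y <- as.factor(train_y)
  if (nlevels(train_y) != 2L) stop("need exactly 2 classes", call. = FALSE)
  if (any(table(train_y) < 1L)) stop("both classes must appear in training", call. = FALSE)
  train_y
}

regularize_cov <- function(S) {
  p <- ncol(S)
  if (!all(is.finite(S)) || rcond(S) < 1e-10) {
    S <- S + diag(1e-6 * sum(diag(S)) / p + 1e-12, p)
    if (rcond(S) < 1e-12) stop("singular class covariance after regularization", call. = FALSE)
  }
  S
}

#' Mahalanobis-distance classifier
#'
#' Assigns each test point to the class whose mean is closest in the
#' Mahalanobis metric of that class's own covariance. Near-singular
#' covariances are ridge-regularized by adding `1e-6 * trace/dim` to the
#' diagonal. Exact distance ties are resolved to the first factor level
#' (the baseline class in this package's pipelines), which avoids inflating
#' sensitivity.
#'
#' @param train_x Numeric matrix or data frame of training features
#'   (rows = records).
#' @param train_y Two-level factor of training labels; the first level is
#'   the negative (baseline) class.
#' @param test_x Test features: vector (one point per feature), matrix or
#'   data frame.
#' @return Factor of predicted labels with the levels of `train_y`.
#' @export
#' @examples
#' x <- matrix(c(rnorm(20, 0), rnorm(20, 5)), ncol = 1)
#' y <- factor(rep(c("BE", "EX"), each = 20), levels = c("BE", "EX"))
#' mahalanobis_classify(x, y, c(0.3, 4.8))
mahalanobis_classify <- function(train_x, train_y, test_x) {
  train_x <- as_matrix_x(train_x)
  train_y <- check_train(train_x, train_y)
  test_x <- as_matrix_x(test_x)
  if (ncol(test_x) != ncol(train_x)) test_x <- matrix(test_x, ncol = ncol(train_x))
  lev <- levels(train_y)
  pooled <- cov(scale(train_x, center = TRUE, scale = FALSE))
  d2 <- vapply(lev, function(cl) {
    xs <- train_x[train_y == cl, , drop = FALSE]
    S <- if (nrow(xs) < 2L) pooled else cov(xs)
    if (!all(is.finite(S))) S <- pooled
    S <- regularize_cov(S)
    mahalanobis(test_x, colMeans(xs), S)
  }, numeric(nrow(test_x)))
  d2 <- matrix(d2, ncol = length(lev))
  # strict inequality: ties go to the first (baseline) level
  factor(ifelse(d2[, 2L] < d2[, 1L], lev[2L], lev[1L]), levels = lev)
}

#' Linear and quadratic discriminant and linear-SVM classifiers
#'
#' Thin wrappers with a common signature around the standard
#' implementations: Gaussian discriminants with shared (`lda_classify`) or
#' per-class (`qda_classify`) covariance from \pkg{MASS}, and a soft-margin
#' linear support vector machine (`svm_classify`, cost fixed at 1) from
#' \pkg{e1071}. The SVM standardizes features using training-fold statistics;
#' the discriminants are scale-equivariant and use none. Posterior ties in
#' the discriminants resolve to the first factor level.
#'
#' The study design is balanced (every subject measured at both stages), so
#' the discriminants use equal priors and the SVM uses balancing class
#' weights. Estimating priors from the training fold would bias every
#' leave-one-out prediction against the held-out record's class -- its class
#' always has one fewer training point -- which drives error rates on
#' effect-free data well below chance.
#'
#' @inheritParams mahalanobis_classify
#' @return Factor of predicted labels.
#' @export
lda_classify <- function(train_x, train_y, test_x) {
  train_x <- as_matrix_x(train_x)
  train_y <- check_train(train_x, train_y)
  test_x <- as_matrix_x(test_x)
  fit <- MASS::lda(train_x, grouping = train_y, prior = c(0.5, 0.5))
  post <- predict(fit, test_x)$posterior
  lev <- levels(train_y)
  factor(ifelse(post[, lev[2L]] > 0.5, lev[2L], lev[1L]), levels = lev)
}

#' @rdname lda_classify
#' @export
qda_classify <- function(train_x, train_y, test_x) {
  train_x <- as_matrix_x(train_x)
  train_y <- check_train(train_x, train_y)
  test_x <- as_matrix_x(test_x)
  if (any(table(train_y) < 2L)) {
    # a single-point class has no covariance of its own: fall back to the
    # shared-covariance discriminant for this fold
    return(lda_classify(train_x, train_y, test_x))
  }
  fit <- MASS::qda(train_x, grouping = train_y, prior = c(0.5, 0.5))
  post <- predict(fit, test_x)$posterior
  lev <- levels(train_y)
  factor(ifelse(post[, lev[2L]] > 0.5, lev[2L], lev[1L]), levels = lev)
}

#' @rdname lda_classify
#' @export
svm_classify <- function(train_x, train_y, test_x) {
  train_x <- as_matrix_x(train_x)
  train_y <- check_train(train_x, train_y)
  test_x <- as_matrix_x(test_x)
  cw <- (length(train_y) / 2) / table(train_y)
  fit <- suppressWarnings(
    e1071::svm(train_x, train_y, kernel = "linear", cost = 1, scale = TRUE,
               class.weights = cw)
  )
  predict(fit, test_x)
}

classifier_funs <- function(names) {
  all <- list(mahalanobis = mahalanobis_classify, lda = lda_classify,
              qda = qda_classify, svm = svm_classify)
  bad <- setdiff(names, names(all))
  if (length(bad)) stop("unknown classifier(s): ", paste(bad, collapse = ", "), call. = FALSE)
  all[names]
}

# Keep a maximal linearly independent subset of (centred) columns so
# rank-deficient feature sets (e.g. a duplicated column) reduce to their
# informative span before LDA/QDA/Mahalanobis.
drop_collinear <- function(x) {
  if (ncol(x) <= 1L) return(x)
  qx <- qr(scale(x, center = TRUE, scale = FALSE))
  keep <- sort(qx$pivot[seq_len(qx$rank)])
  x[, keep, drop = FALSE]
}

#' Leave-one-out cross-validated confusion counts
#'
#' Each record is predicted by models trained on all remaining records; the
#' confusion counts are accumulated over folds. The positive class is the
#' second factor level of `labels` (the post-exercise class in this
#' package's pipelines).
#'
#' @param x Feature matrix or data frame (rows = records).
#' @param labels Two-level factor; second level = positive class.
#' @param classifiers Character subset of
#'   `c("mahalanobis", "lda", "qda", "svm")`.
#' @return Tibble with one row per classifier: `classifier`, `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
#' @examples
#' x <- c(-1.0, -1.1, 1.0, 1.1)
#' y <- factor(c("BE", "BE", "EX", "EX"), levels = c("BE", "EX"))
#' loocv_confusion(x, y, classifiers = c("mahalanobis", "lda"))
loocv_confusion <- function(x, labels,
                            classifiers = c("mahalanobis", "lda", "qda", "svm")) {
  x <- drop_collinear(as_matrix_x(x))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L || any(table(labels) < 2L)) {
    stop("labels must contain 2 classes with at least 2 records each", call. = FALSE)
  }
  funs <- classifier_funs(classifiers)
  n <- nrow(x)
  if (length(labels) != n) stop("length(labels) must match nrow(x)", call. = FALSE)
  pos <- levels(labels)[2L]
  counts <- matrix(0L, nrow = length(funs), ncol = 4L,
                   dimnames = list(names(funs), c("tp", "fp", "fn", "tn")))
  for (i in seq_len(n)) {
    tr_x <- x[-i, , drop = FALSE]
    tr_y <- labels[-i]
    for (cl in names(funs)) {
      pred <- as.character(funs[[cl]](tr_x, tr_y, x[i, , drop = FALSE]))[1L]
      truth <- as.character(labels[i])
      slot <- if (truth == pos && pred == pos) "tp"
              else if (truth != pos && pred == pos) "fp"
              else if (truth == pos && pred != pos) "fn"
              else "tn"
      counts[cl, slot] <- counts[cl, slot] + 1L
    }
  }
  tibble::tibble(classifier = rownames(counts),
                 tp = unname(counts[, "tp"]), fp = unname(counts[, "fp"]),
                 fn = unname(counts[, "fn"]), tn = unname(counts[, "tn"]))
}

#' Sensitivity, positive predictivity and F1 from confusion counts
#'
#' `SE = TP / (TP + FN)`, `PP = TP / (TP + FP)` and
#' `F1 = 2 * SE * PP / (SE + PP)`, all in percent. SE or PP with a zero
#' denominator is undefined and returned as `NA` (not 0). F1 is evaluated
#' in its count form `2 TP / (2 TP + FP + FN)` -- algebraically identical
#' to the harmonic mean whenever both SE and PP are defined -- so it stays
#' defined (and equal to 0) when a classifier makes no positive prediction
#' but positives exist.
#'
#' @param tp,fp,fn Confusion counts (vectorized).
#' @return Tibble with columns `se`, `pp`, `f1` in percent.
#' @export
#' @examples
#' classification_metrics(tp = 33, fp = 11, fn = 7)
classification_metrics <- function(tp, fp, fn) {
  se <- ifelse(tp + fn > 0, 100 * tp / (tp + fn), NA_real_)
  pp <- ifelse(tp + fp > 0, 100 * tp / (tp + fp), NA_real_)
  f1 <- ifelse(2 * tp + fp + fn > 0, 100 * 2 * tp / (2 * tp + fp + fn), NA_real_)
  tibble::tibble(se = se, pp = pp, f1 = f1)
}

#' Overall accuracy from a grid of F1 scores
#'
#' The overall accuracy (OA) of one feature is the arithmetic mean of its
#' F1 scores over all classifier-by-comparison cells (12 cells for 4
#' classifiers and 3 comparisons), rounded to 2 decimals.
#'
#' @param f1 Numeric vector of F1 percentages; no missing cells allowed.
#' @return OA in percent.
#' @export
#' @examples
#' overall_accuracy(rep(50, 12))
overall_accuracy <- function(f1) {
  if (length(f1) == 0L || anyNA(f1)) stop("all F1 cells must be present", call. = FALSE)
  round(mean(f1), 2)
}

#' Per-feature leave-one-out classification report
#'
#' The classification harness: for every feature and every baseline vs
#' post-exercise comparison, runs leave-one-out cross-validation with each
#' classifier and reports confusion counts, SE, PP and F1, plus each
#' feature's overall accuracy (mean F1 across all cells).
#'
#' @param features Feature tibble from [extract_cohort_features()].
#' @param classifiers Character subset of
#'   `c("mahalanobis", "lda", "qda", "svm")`.
#' @param feature_cols Columns to classify on; defaults to the 14 of
#'   [ppg_feature_names()].
#' @return An object of class `heat_classification`: list with `cells` (one
#'   row per feature x comparison x classifier) and `oa` (one row per
#'   feature). Use [tidy()] / [glance()] to extract them.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 6, seed = 11))
#' cls <- classify_features(extract_cohort_features(cohort),
#'                          classifiers = "lda")
#' glance(cls)
classify_features <- function(features,
                              classifiers = c("mahalanobis", "lda", "qda", "svm"),
                              feature_cols = ppg_feature_names()) {
  stopifnot(all(c("subject_id", "stage") %in% names(features)))
  missing_cols <- setdiff(feature_cols, names(features))
  if (length(missing_cols)) {
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ex_stages <- setdiff(levels(factor(features$stage)), "BE")
  cells <- purrr::map(feature_cols, function(f) {
    purrr::map(ex_stages, function(st) {
      sub <- features[features$stage %in% c("BE", st), ]
      y <- factor(ifelse(sub$stage == "BE", "BE", "stressed"),
                  levels = c("BE", "stressed"))
      conf <- loocv_confusion(sub[[f]], y, classifiers = classifiers)
      dplyr::bind_cols(
        tibble::tibble(feature = f, comparison = paste0("BE_vs_", st)),
        conf,
        classification_metrics(conf$tp, conf$fp, conf$fn)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  oa <- cells |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(oa = overall_accuracy(.data$f1), .groups = "drop") |>
    dplyr::arrange(match(.data$feature, feature_cols))
  structure(list(cells = cells, oa = oa), class = "heat_classification")
}

#' @export
print.heat_classification <- function(x, ...) {
  cat("<heat_classification>\n")
  best <- x$oa[which.max(x$oa$oa), ]
  cat(sprintf("  %d features x %d cells each; best: %s (OA = %.2f%%)\n",
              nrow(x$oa), nrow(x$cells) / max(1L, nrow(x$oa)),
              best$feature, best$oa))
  invisible(x)
}

#' @export
tidy.heat_classification <- function(x, ...) x$cells

#' @export
glance.heat_classification <- function(x, ...) x$oa

#' Rank features by overall accuracy
#'
#' Orders the features of a classification report by OA descending. Ties
#' break by the mean F1 on the last comparison, then by feature name.
#'
#' @param classification A [classify_features()] result.
#' @return Tibble `feature`, `oa`, sorted best first.
#' @export
rank_features <- function(classification) {
  stopifnot(inherits(classification, "heat_classification"))
  cells <- classification$cells
  last_cmp <- sort(unique(cells$comparison))
  last_cmp <- last_cmp[length(last_cmp)]
  tie <- cells |>
    dplyr::filter(.data$comparison == last_cmp) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(f1_last = mean(.data$f1), .groups = "drop")
  classification$oa |>
    dplyr::left_join(tie, by = "feature") |>
    dplyr::arrange(dplyr::desc(.data$oa), dplyr::desc(.data$f1_last), .data$feature) |>
    dplyr::select("feature", "oa")
}

#' Leave-one-out classification of a feature pair
#'
#' Classifies records from a two-feature vector (e.g. the aa energy
#' combined with RMSSD) for each baseline vs post-exercise comparison.
#' Linear discriminant analysis is the default classifier for combined
#' features; any of the four classifiers can be requested.
#'
#' @param features Feature tibble from [extract_cohort_features()].
#' @param cols Character vector of exactly two feature column names.
#' @param classifiers Classifier name(s); default `"lda"`.
#' @return Tibble with one row per comparison x classifier: confusion
#'   counts, `se`, `pp`, `f1`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 6, seed = 11))
#' classify_feature_pair(extract_cohort_features(cohort),
#'                       c("energy_aa_ppg", "rmssd"))
classify_feature_pair <- function(features, cols, classifiers = "lda") {
  stopifnot(length(cols) == 2L, all(cols %in% names(features)))
  ex_stages <- setdiff(levels(factor(features$stage)), "BE")
  purrr::map(ex_stages, function(st) {
    sub <- features[features$stage %in% c("BE", st), ]
    keep <- complete.cases(sub[, cols])
    sub <- sub[keep, ]
    y <- factor(ifelse(sub$stage == "BE", "BE", "stressed"),
                levels = c("BE", "stressed"))
    conf <- loocv_confusion(sub[, cols], y, classifiers = classifiers)
    dplyr::bind_cols(
      tibble::tibble(pair = paste(cols, collapse = "+"),
                     comparison = paste0("BE_vs_", st)),
      conf,
      classification_metrics(conf$tp, conf$fp, conf$fn)
    )
  }) |> purrr::list_rbind()
}
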