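two_class <- function(x, labels = NULL) {
  if (is.null(labels)) labels <- rep(c("BE", "EX"), each = length(x) / 2)
  factor(labels, levels = c("BE", "EX"))
}

test_that("Mahalanobis classification reduces to nearest mean under equal variance", {
  x <- matrix(c(-0.5, 0.5, 9.5, 10.5), ncol = 1)
  y <- two_class(x)
  expect_equal(as.character(mahalanobis_classify(x, y, 2)), "BE")
  expect_equal(as.character(mahalanobis_classify(x, y, 8)), "EX")
  # exact tie resolves to the baseline class
  expect_equal(as.character(mahalanobis_classify(x, y, 5)), "BE")
})

test_that("Mahalanobis with identity covariances equals the nearest-mean oracle", {
  set.seed(91)
  # construct classes whose sample covariance is exactly identity
  base <- matrix(c(1, 0, -1, 0, 0, 1, 0, -1), ncol = 2, byrow = TRUE)
  base <- sweep(base, 2, colMeans(base))
  base <- base %*% solve(chol(cov(base))) # whitened: cov = I
  x <- rbind(base, sweep(base, 2, c(3, -2), `+`))
  y <- two_class(x[, 1], rep(c("BE", "EX"), each = 4))
  tests <- matrix(rnorm(200), ncol = 2)
  pred <- mahalanobis_classify(x, y, tests)
  mu_be <- colMeans(x[1:4, ])
  mu_ex <- colMeans(x[5:8, ])
  d_be <- rowSums(sweep(tests, 2, mu_be)^2)
  d_ex <- rowSums(sweep(tests, 2, mu_ex)^2)
  oracle <- ifelse(d_ex < d_be, "EX", "BE")
  expect_equal(as.character(pred), oracle)
})

test_that("all four classifiers are perfect on linearly separated data", {
  x <- c(-1.2, -1.0, -0.8, 0.8, 1.0, 1.2)
  y <- two_class(x)
  for (f in list(mahalanobis_classify, lda_classify, qda_classify, svm_classify)) {
    expect_equal(as.character(f(x, y, c(-1.1, 1.1))), c("BE", "EX"))
  }
})

test_that("LDA thresholds at the midpoint for equal-prior, equal-spread classes", {
  x <- c(-2, -1, 0, 4, 5, 6)
  y <- two_class(x)
  mid <- (mean(x[1:3]) + mean(x[4:6])) / 2
  expect_equal(as.character(lda_classify(x, y, mid - 0.05)), "BE")
  expect_equal(as.character(lda_classify(x, y, mid + 0.05)), "EX")
})

test_that("QDA equals LDA when per-class covariances are identical", {
  set.seed(92)
  a <- matrix(rnorm(60), ncol = 2)
  x <- rbind(a, sweep(a, 2, c(2.5, 1.0), `+`))  # shifted copy: equal class covs
  y <- two_class(x[, 1], rep(c("BE", "EX"), each = 30))
  tests <- matrix(rnorm(200, 1), ncol = 2)
  expect_equal(as.character(qda_classify(x, y, tests)),
               as.character(lda_classify(x, y, tests)))
})

test_that("degenerate training folds are rejected", {
  y_missing <- factor(c("A", "A", "A"), levels = c("A", "B"))
  expect_error(mahalanobis_classify(c(1, 2, 3), y_missing, 1), "both classes")
  expect_error(lda_classify(c(1, 2, 3, 4), factor(rep("A", 4)), 1), "2 classes")
})

test_that("LOOCV confusion counts match a hand-run of each fold", {
  x <- c(-1.0, -1.1, 1.0, 1.1)
  y <- two_class(x)
  conf <- loocv_confusion(x, y)
  expect_equal(conf$tp, rep(2L, 4))
  expect_equal(conf$tn, rep(2L, 4))
  expect_equal(conf$fp, rep(0L, 4))
  expect_equal(conf$fn, rep(0L, 4))
  expect_equal(conf$tp + conf$fp + conf$fn + conf$tn, rep(length(x), 4))
})

test_that("LOOCV is invariant to record order and rejects one-class input", {
  set.seed(93)
  x <- c(rnorm(8, 0), rnorm(8, 1.5))
  y <- two_class(x)
  conf1 <- loocv_confusion(x, y, classifiers = c("mahalanobis", "lda"))
  perm <- sample(length(x))
  conf2 <- loocv_confusion(x[perm], y[perm], classifiers = c("mahalanobis", "lda"))
  expect_equal(conf1, conf2)
  expect_error(loocv_confusion(x, factor(rep("BE", 16))), "2 classes")
})

test_that("metrics follow the SE/PP/F1 definitions", {
  m <- classification_metrics(tp = 40, fp = 0, fn = 0)
  expect_equal(unlist(m), c(se = 100, pp = 100, f1 = 100))
  # harmonic mean of the published example operating point
  m2 <- classification_metrics(tp = 33, fp = 11, fn = 7)
  expect_equal(m2$se, 82.5)
  expect_equal(m2$pp, 75)
  expect_equal(round(m2$f1, 2), 78.57)
  m3 <- classification_metrics(tp = 0, fp = 3, fn = 5)
  expect_equal(unlist(m3), c(se = 0, pp = 0, f1 = 0))
  # no positive prediction: PP undefined, F1 defined by the count form
  m4 <- classification_metrics(tp = 0, fp = 0, fn = 5)
  expect_equal(m4$se, 0)
  expect_true(is.na(m4$pp))
  expect_equal(m4$f1, 0)
})

test_that("F1 is the harmonic mean: F1(x, x) = x", {
  for (tp in c(1, 10, 25)) {
    m <- classification_metrics(tp = tp, fp = 5, fn = 5)
    expect_equal(m$se, m$pp)
    expect_equal(m$f1, m$se)
  }
})

test_that("overall accuracy averages a complete F1 grid", {
  expect_equal(overall_accuracy(rep(50, 12)), 50)
  expect_error(overall_accuracy(c(rep(50, 11), NA)), "present")
})

test_that("a duplicated feature pair reproduces single-feature decisions", {
  feats <- small_features()
  single <- classify_feature_pair(
    dplyr::mutate(feats, copy = .data$energy_aa_ppg),
    c("energy_aa_ppg", "copy"), classifiers = "lda"
  )
  ref <- classify_features(feats, classifiers = "lda",
                           feature_cols = "energy_aa_ppg")$cells
  expect_equal(single$tp, ref$tp)
  expect_equal(single$fp, ref$fp)
  expect_equal(single$f1, ref$f1)
})

test_that("a well-separated feature pair is classified perfectly", {
  feats <- small_features()
  feats$sep <- ifelse(feats$stage == "BE", 0, 50) + rnorm(nrow(feats))
  feats$sep2 <- feats$sep + rnorm(nrow(feats))
  out <- classify_feature_pair(feats, c("sep", "sep2"))
  expect_true(all(out$se == 100))
  expect_true(all(out$pp == 100))
})

test_that("classification report covers every feature-comparison-classifier cell", {
  cls <- cached("small_classification",
                classify_features(small_features(),
                                  classifiers = c("mahalanobis", "lda")))
  cells <- tidy(cls)
  expect_equal(nrow(cells), 14L * 3L * 2L)
  expect_true(all(cells$tp + cells$fp + cells$fn + cells$tn == 16L))
  oa <- glance(cls)
  expect_equal(nrow(oa), 14L)
  expect_true(all(oa$oa >= 0 & oa$oa <= 100))
  rk <- rank_features(cls)
  expect_equal(sort(rk$oa, decreasing = TRUE), rk$oa)
})
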