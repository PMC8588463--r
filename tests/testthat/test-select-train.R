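# Feature selection, class weighting, classifier families, evaluation.

blobTable <- function(n = 60, sep = 4, classes = 2, p = 4, seed = 1,
                      subjects = 6) {
  set.seed(seed)
  y <- rep(paste0("class", seq_len(classes)), each = n)
  x <- matrix(rnorm(classes * n * p), classes * n, p)
  for (k in seq_len(classes)) x[y == paste0("class", k), 1:2] <-
    x[y == paste0("class", k), 1:2] + (k - 1) * sep
  cols <- featureColumns()
  mat <- matrix(0, length(cols), classes * n,
                dimnames = list(cols, paste0("epoch", seq_len(classes * n))))
  feats <- cols[seq_len(p)]
  mat[feats, ] <- t(x)
  ft <- methods::as(SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(features = mat),
    colData = S4Vectors::DataFrame(
      subject = rep(paste0("S", seq_len(subjects)),
                    length.out = classes * n),
      state = y)), "FeatureTable")
  list(ft = ft, features = feats)
}

test_that("F-test importance separates strong, null and constant features", {
  set.seed(12)
  n <- 50
  cols <- featureColumns()
  mat <- matrix(rnorm(149 * 2 * n), 149, 2 * n, dimnames = list(cols, NULL))
  y <- rep(c("a", "b"), each = n)
  mat[1, ] <- rnorm(2 * n) + ifelse(y == "a", 0, 10)  # 10 within-class SDs
  mat[2, ] <- 1                                        # constant -> screened
  ft <- methods::as(SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(features = mat),
    colData = S4Vectors::DataFrame(subject = rep("S1", 2 * n), state = y)),
    "FeatureTable")
  imp <- featureImportanceFtest(ft)
  expect_true(imp$selected[1])
  expect_gt(imp$importance[1], 0.95)
  expect_true(imp$screened[2])
  expect_true(is.na(imp$F[2]))
  # identical-distribution features are mostly unselected
  expect_lt(mean(imp$selected[-(1:2)]), 0.2)
})

test_that("ANOVA-F selection agrees with a permutation oracle on 20 features", {
  set.seed(13)
  n <- 40
  y <- factor(rep(c("a", "b"), each = n))
  agree <- 0
  for (f in 1:20) {
    v <- rnorm(2 * n) + if (f <= 10) ifelse(y == "a", 0, 2) else 0
    p <- stats::oneway.test(v ~ y, var.equal = TRUE)$p.value
    selF <- (1 - p) > 0.95
    selPerm <- permutationImportance(v, y, nPerm = 200, seed = f) > 0.95
    agree <- agree + (selF == selPerm)
  }
  expect_gte(agree, 19)
})

test_that("class weights are inverse-frequency, normalized to mean one", {
  w <- classWeights(rep(c("a", "b", "c"), each = 10))
  expect_equal(unname(w), rep(1, 3))
  w2 <- classWeights(rep(c("rest", "city", "exp"), c(51, 459, 306)))
  expect_equal(unname(w2["rest"]), 816 / (3 * 51), tolerance = 1e-9)
  expect_equal(unname(w2["city"]), 816 / (3 * 459), tolerance = 1e-9)
  expect_gt(w2[["rest"]], w2[["exp"]])
  expect_gt(w2[["exp"]], w2[["city"]])
  # weights are normalized: weighted row count equals the raw row count
  counts <- c(city = 459, exp = 306, rest = 51)
  expect_equal(sum(w2[names(counts)] * counts), 816, tolerance = 1e-9)
  expect_equal(unname(classWeights(rep("only", 5))), 1)
})

test_that("subject-wise splitting rejects overlap and keeps rows disjoint", {
  ft <- smallFeatureTable(seed = 41, nSubjects = 4,
                          eps = c(resting = 2L, city_roadway = 2L,
                                  expressway = 2L))
  subj <- unique(SummarizedExperiment::colData(ft)$subject)
  parts <- splitBySubject(ft, subj[1:3], subj[4])
  expect_equal(ncol(parts$train) + ncol(parts$test), ncol(ft))
  expect_length(intersect(SummarizedExperiment::colData(parts$train)$subject,
                          SummarizedExperiment::colData(parts$test)$subject),
                0)
  expect_error(splitBySubject(ft, subj[1:3], subj[3:4]), "overlap")
  expect_error(splitBySubject(ft, subj, character()), "at least one")
  expect_error(splitBySubject(ft, subj[1:2], subj[4]), "not assigned")
})

test_that("every model family separates two distant Gaussian blobs", {
  blob <- blobTable(n = 40, sep = 5, seed = 14)
  for (kind in c("knn", "lda", "svm", "tree_gain_ratio", "tree_univariate")) {
    fit <- trainClassifier(kind, blob$ft, features = blob$features,
                           cvK = 5, seed = 3)
    expect_gt(fit@cvAccuracy, 0.95)
  }
})

test_that("permuted labels give chance-level accuracy", {
  set.seed(15)
  blob <- blobTable(n = 30, sep = 0, classes = 3, seed = 16)
  fit <- trainClassifier("lda", blob$ft, features = blob$features,
                         cvK = 5, seed = 4)
  expect_lt(abs(fit@cvAccuracy - 1 / 3), 0.1)
})

test_that("training is deterministic given the seed", {
  blob <- blobTable(n = 30, sep = 2, seed = 17)
  a <- trainClassifier("knn", blob$ft, features = blob$features, cvK = 5,
                       seed = 7)
  b <- trainClassifier("knn", blob$ft, features = blob$features, cvK = 5,
                       seed = 7)
  expect_identical(a@foldAccuracy, b@foldAccuracy)
  expect_identical(a@cvAccuracy, b@cvAccuracy)
})

test_that("fold count shrinks to the smallest class with a warning", {
  blob <- blobTable(n = 4, sep = 5, seed = 18)
  expect_warning(fit <- trainClassifier("lda", blob$ft,
                                        features = blob$features,
                                        cvK = 10, seed = 1),
                 "reduced")
  expect_length(fit@foldAccuracy, 4)
})

test_that("repeated k-fold accuracies vary little on fixed data", {
  blob <- blobTable(n = 40, sep = 3, seed = 19)
  accs <- repeatedCvAccuracy("lda", blob$ft, features = blob$features,
                             cvK = 5, repeats = 3, seed = 5)
  expect_lt(max(accs) - min(accs), 0.05)
})

test_that("confusion accuracies reproduce every published matrix", {
  # training/testing confusion matrices (actual rows: city, expressway,
  # resting) with their printed per-class accuracies
  published <- list(
    knn_train = list(m = rbind(c(234, 59, 2), c(74, 191, 0), c(2, 0, 31)),
                     per = c(79.32, 72.08, 93.94)),
    knn_test = list(m = rbind(c(88, 50, 1), c(36, 53, 0), c(2, 0, 16)),
                    per = c(63.31, 59.55, 88.89)),
    lda_train = list(m = rbind(c(214, 80, 1), c(82, 182, 1), c(2, 0, 31)),
                     per = c(72.54, 68.68, 93.94), overall = 72.01),
    lda_test = list(m = rbind(c(87, 50, 2), c(29, 59, 1), c(1, 1, 16)),
                    per = c(62.59, 66.29, 88.89)),
    svm_train = list(m = rbind(c(242, 53, 0), c(72, 193, 0), c(0, 0, 33)),
                     per = c(82.03, 72.83, 100), overall = 78.92),
    svm_test = list(m = rbind(c(96, 42, 1), c(33, 56, 0), c(1, 0, 17)),
                    per = c(69.06, 62.92, 94.44), overall = 68.70),
    c50_train = list(m = rbind(c(285, 10, 0), c(11, 254, 0), c(0, 0, 33)),
                     per = c(96.61, 95.85, 100), overall = 96.46),
    c50_test = list(m = rbind(c(82, 56, 1), c(27, 61, 1), c(1, 1, 16)),
                    per = c(58.99, 68.54, 88.89)),
    quest_train = list(m = rbind(c(217, 76, 2), c(108, 151, 6), c(0, 0, 33)),
                       per = c(73.56, 56.98, 100)),
    quest_test = list(m = rbind(c(88, 48, 3), c(34, 53, 2), c(0, 0, 18)),
                      per = c(63.31, 59.55, 100)))
  for (nm in names(published)) {
    pub <- published[[nm]]
    acc <- accuracyFromConfusion(pub$m)
    expect_equal(round(100 * unname(acc$per_class), 2), pub$per,
                 tolerance = 0.01, label = nm)
    if (!is.null(pub$overall))
      expect_equal(round(100 * acc$overall, 2), pub$overall,
                   tolerance = 0.01, label = nm)
  }
  expect_equal(accuracyFromConfusion(diag(3))$overall, 1)
  expect_error(accuracyFromConfusion(matrix(0, 2, 2)), "empty")
  expect_error(accuracyFromConfusion(matrix(1, 2, 3)), "square")
})

test_that("trapezoid AUC equals the exhaustive pair-counting oracle", {
  set.seed(20)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(labels) || all(labels)) next
    scores <- round(rnorm(n), 1)   # rounding forces ties
    expect_equal(aucTrapezoid(scores, labels), pairCountAUC(scores, labels),
                 tolerance = 1e-12)
  }
  # cross-check against the reference ROC implementation
  skip_if_not_installed("pROC")
  set.seed(21)
  labels <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  scores <- rnorm(100) + labels
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(labels, scores))))
  expect_equal(aucTrapezoid(scores, labels), ref, tolerance = 1e-9)
})

test_that("chance-level scores give AUC one half and Gini zero", {
  set.seed(22)
  aucs <- replicate(30, {
    labels <- rep(c(TRUE, FALSE), each = 100)
    aucTrapezoid(rnorm(200), labels)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  expect_equal(giniFromAuc(0.667), 0.334)
  expect_equal(giniFromAuc(1), 1)
  expect_equal(giniFromAuc(0.5), 0)
})

test_that("a perfect classifier yields a diagonal report with AUC 1", {
  blob <- blobTable(n = 40, sep = 8, seed = 23)
  fit <- trainClassifier("lda", blob$ft, features = blob$features, cvK = 5,
                         seed = 2)
  rep_ <- evaluateClassifier(fit, blob$ft)
  expect_equal(rep_@overallAccuracy, 1)
  expect_true(all(rep_@confusion[upper.tri(rep_@confusion)] == 0))
  expect_true(all(rep_@confusion[lower.tri(rep_@confusion)] == 0))
  expect_equal(rep_@auc, 1)
  expect_equal(rep_@gini, 1)
  expect_equal(rep_@gini, 2 * rep_@auc - 1)
  expect_equal(sum(rep_@confusion), ncol(blob$ft))
})

test_that("permutation importance concentrates on the informative features", {
  blob <- blobTable(n = 50, sep = 5, seed = 24)
  fit <- trainClassifier("knn", blob$ft, features = blob$features, cvK = 5,
                         seed = 2)
  rep_ <- evaluateClassifier(fit, blob$ft, importance = TRUE, seed = 3)
  expect_equal(sum(rep_@importance), 1, tolerance = 1e-9)
  # the two shifted columns carry the separation
  top2 <- names(sort(rep_@importance, decreasing = TRUE))[1:2]
  expect_setequal(top2, blob$features[1:2])
})
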