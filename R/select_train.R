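# Feature selection, subject-wise partitioning, class weighting, and the
# five classifier families with stratified 10-fold cross-validation and
# confusion-matrix / ROC reporting.

.tableToXy <- function(ft, features = NULL) {
  mat <- SummarizedExperiment::assay(ft, "features")
  if (is.null(features)) features <- rownames(mat)
  x <- t(mat[features, , drop = FALSE])
  y <- factor(SummarizedExperiment::colData(ft)$state)
  list(x = x, y = y, subject = SummarizedExperiment::colData(ft)$subject)
}

#' ANOVA F-test feature importance
#'
#' Screens out constant and missing-value features, then scores every
#' remaining feature with a one-way ANOVA F-test across the class labels.
#' Importance is `1 - p`; a feature is selected when its importance exceeds
#' the threshold (default 0.95).
#'
#' @param ft a [FeatureTable-class] (training partition).
#' @param threshold importance cut-off for selection.
#' @return data.frame with columns `feature`, `F`, `p`, `importance`,
#'   `selected`, `screened` (constant/missing features are screened, not
#'   scored).
#' @export
featureImportanceFtest <- function(ft, threshold = 0.95) {
  xy <- .tableToXy(ft)
  y <- xy$y
  if (nlevels(y) < 2) stop("need >= 2 classes")
  if (any(table(y) < 2)) stop("need >= 2 rows per class")
  out <- do.call(rbind, lapply(colnames(xy$x), function(f) {
    v <- xy$x[, f]
    if (anyNA(v) || sd(v) == 0)
      return(data.frame(feature = f, F = NA_real_, p = NA_real_,
                        importance = NA_real_, selected = FALSE,
                        screened = TRUE))
    fit <- stats::oneway.test(v ~ y, var.equal = TRUE)
    p <- fit$p.value
    data.frame(feature = f, F = unname(fit$statistic), p = p,
               importance = 1 - p, selected = (1 - p) > threshold,
               screened = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Subject-wise train/test split
#'
#' Partitions epochs by subject identifier so that no subject contributes to
#' both partitions (leakage-safe for subject-level effects).
#'
#' @param ft a [FeatureTable-class].
#' @param trainSubjects,testSubjects disjoint subject ID sets covering all
#'   rows.
#' @return list with `train` and `test` [FeatureTable-class] objects.
#' @export
splitBySubject <- function(ft, trainSubjects, testSubjects) {
  if (length(intersect(trainSubjects, testSubjects)))
    stop("train and test subject sets overlap")
  if (!length(trainSubjects) || !length(testSubjects))
    stop("both partitions need at least one subject")
  subj <- SummarizedExperiment::colData(ft)$subject
  missing <- setdiff(unique(subj), c(trainSubjects, testSubjects))
  if (length(missing))
    stop("subjects not assigned to a partition: ",
         paste(missing, collapse = ", "))
  list(train = ft[, subj %in% trainSubjects],
       test = ft[, subj %in% testSubjects])
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (K * n_c)`, normalized to mean 1: minority classes (the short
#' resting segments) are up-weighted, majority driving classes down-weighted.
#'
#' @param labels class label vector.
#' @return named numeric weights.
#' @examples
#' classWeights(rep(c("rest", "city", "exp"), c(51, 459, 306)))
#' @export
classWeights <- function(labels) {
  tab <- table(labels)
  if (any(tab == 0)) tab <- tab[tab > 0]
  w <- sum(tab) / (length(tab) * tab)
  setNames(as.numeric(w), names(tab))
}

.stratifiedFolds <- function(y, k, seed) {
  minClass <- min(table(y))
  if (k > minClass) {
    warning(sprintf("cv_k reduced from %d to smallest class count %d",
                    k, minClass))
    k <- minClass
  }
  fold <- integer(length(y))
  set.seed(seed)
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  list(fold = fold, k = k)
}

.fitOne <- function(kind, x, y, w, seed) {
  switch(kind,
    knn = .knnModel(x, y, w, k = 3),
    lda = MASS::lda(x, grouping = y, prior = w[levels(y)] *
                      as.numeric(table(y)[levels(y)]) /
                      sum(w[levels(y)] * as.numeric(table(y)[levels(y)]))),
    svm = e1071::svm(x, y, kernel = "radial", scale = FALSE,
                     class.weights = w[levels(y)], probability = FALSE),
    tree_gain_ratio = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- y
      set.seed(seed)  # rpart's internal cross-validation folds
      fit <- rpart::rpart(.y ~ ., df, weights = unname(w[as.character(y)]),
                          method = "class",
                          parms = list(split = "information"),
                          control = rpart::rpart.control(cp = 1e-3,
                                                         xval = 10))
      cp <- fit$cptable
      best <- cp[which.min(cp[, "xerror"]), "CP"]
      rpart::prune(fit, cp = best)
    },
    tree_univariate = .univariateTree(x, y, w),
    stop("unknown classifier kind: ", kind))
}

.predictOne <- function(kind, fit, newx, levels) {
  switch(kind,
    knn = .knnPredict(fit, newx),
    lda = predict(fit, newx)$class,
    svm = predict(fit, newx),
    tree_gain_ratio = predict(fit, data.frame(newx, check.names = FALSE),
                              type = "class"),
    tree_univariate = .utreePredict(fit, newx))
}

# positive-class score for ROC construction (binary tasks)
.scoreOne <- function(kind, fit, newx, positive) {
  switch(kind,
    knn = .knnScores(fit, newx)$votes[, positive],
    lda = predict(fit, newx)$posterior[, positive],
    svm = {
      dv <- attr(predict(fit, newx, decision.values = TRUE),
                 "decision.values")
      s <- dv[, 1]
      # orient toward the requested positive class
      if (!startsWith(colnames(dv)[1], paste0(positive, "/"))) s <- -s
      s
    },
    tree_gain_ratio = predict(fit, data.frame(newx, check.names = FALSE),
                              type = "prob")[, positive],
    tree_univariate = .utreeProb(fit, newx)[, positive])
}

#' Train one classifier family with cross-validation
#'
#' Standardizes features (z-score from the training partition) for the
#' distance/kernel families (KNN, LDA, RBF-SVM); tree families see raw
#' values. Class imbalance is handled with inverse-frequency weights: prior
#' probabilities for LDA, kernel class weights for the SVM, case weights for
#' the gain-ratio tree, vote/leaf weights for KNN and the univariate tree.
#' Reports mean stratified k-fold cross-validation accuracy; fold assignment
#' is a pure function of the seed.
#'
#' @param kind one of `"knn"`, `"lda"`, `"svm"`, `"tree_gain_ratio"`
#'   (gain-style information split with cost-complexity pruning),
#'   `"tree_univariate"` (ANOVA-selected univariate binary splits).
#' @param ft training [FeatureTable-class].
#' @param features feature names to use (e.g. the selected set); default all.
#' @param weights named class weights; default [classWeights()] of the
#'   training labels.
#' @param cvK number of cross-validation folds.
#' @param seed integer seed controlling fold shuffling.
#' @return a [ClassifierFit-class].
#' @export
trainClassifier <- function(kind, ft, features = NULL, weights = NULL,
                            cvK = 10, seed = 1) {
  xy <- .tableToXy(ft, features)
  x <- xy$x
  y <- droplevels(xy$y)
  keep <- complete.cases(x)
  x <- x[keep, , drop = FALSE]
  y <- droplevels(y[keep])
  if (is.null(weights)) weights <- classWeights(y)
  standardized <- kind %in% c("knn", "lda", "svm")
  if (standardized) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl == 0] <- 1
    xs <- scale(x, ctr, scl)
  } else {
    ctr <- numeric()
    scl <- numeric()
    xs <- x
  }
  folds <- .stratifiedFolds(y, cvK, seed)
  foldAcc <- vapply(seq_len(folds$k), function(f) {
    tr <- folds$fold != f
    fit <- .fitOne(kind, xs[tr, , drop = FALSE], droplevels(y[tr]), weights,
                   seed + f)
    pred <- .predictOne(kind, fit, xs[!tr, , drop = FALSE], levels(y))
    mean(as.character(pred) == as.character(y[!tr]))
  }, numeric(1))
  fit <- .fitOne(kind, xs, y, weights, seed)
  new("ClassifierFit", kind = kind, fit = fit, center = ctr, scale = scl,
      featureNames = colnames(x), classLevels = levels(y),
      classWeights = weights, cvAccuracy = mean(foldAcc),
      foldAccuracy = foldAcc, seed = as.integer(seed))
}

#' Repeated cross-validation accuracy
#'
#' Mean cross-validated accuracy over `repeats` re-shufflings of the fold
#' assignment (seeded deterministically from `seed`).
#'
#' @inheritParams trainClassifier
#' @param repeats number of repetitions.
#' @return numeric vector of per-repeat mean CV accuracies.
#' @export
repeatedCvAccuracy <- function(kind, ft, features = NULL, weights = NULL,
                               cvK = 10, repeats = 3, seed = 1) {
  vapply(seq_len(repeats), function(r)
    trainClassifier(kind, ft, features, weights, cvK,
                    seed = seed + 1000 * r)@cvAccuracy,
    numeric(1))
}

.predictTable <- function(model, ft) {
  xy <- .tableToXy(ft, model@featureNames)
  x <- xy$x
  if (length(model@center)) x <- scale(x, model@center, model@scale)
  list(x = x, y = factor(as.character(xy$y), levels = model@classLevels))
}

#' Evaluate a fitted classifier on a held-out table
#'
#' Builds the actual x predicted confusion matrix and per-class/overall
#' accuracies. For binary tasks, also the ROC curve from the model's
#' positive-class scores, trapezoid AUC and Gini = 2 AUC - 1. Predictor
#' importances are estimated by permutation (accuracy drop when one feature
#' column is shuffled), for every model family alike.
#'
#' @param model a [ClassifierFit-class].
#' @param ft test [FeatureTable-class] with the training feature schema.
#' @param importance compute permutation importances (slower).
#' @param importanceRepeats permutations per feature.
#' @param seed seed for the permutations.
#' @return a [ClassifierReport-class].
#' @export
evaluateClassifier <- function(model, ft, importance = FALSE,
                               importanceRepeats = 1, seed = 1) {
  pt <- .predictTable(model, ft)
  ok <- complete.cases(pt$x) & !is.na(pt$y)
  x <- pt$x[ok, , drop = FALSE]
  y <- droplevels(pt$y[ok])
  pred <- .predictOne(model@kind, model@fit, x, model@classLevels)
  lev <- model@classLevels
  conf <- table(actual = factor(as.character(y), levels = lev),
                predicted = factor(as.character(pred), levels = lev))
  conf <- unclass(conf)
  acc <- accuracyFromConfusion(conf)
  task <- if (length(lev) == 2) paste(lev, collapse = "_vs_") else "multiclass"
  if (length(lev) == 2 && nlevels(y) == 2) {
    positive <- lev[2]
    sc <- .scoreOne(model@kind, model@fit, x, positive)
    roc <- rocCurve(sc, y == positive)
    auc <- aucTrapezoid(sc, y == positive)
    gini <- giniFromAuc(auc)
  } else {
    roc <- data.frame(fpr = numeric(), tpr = numeric())
    auc <- NA_real_
    gini <- NA_real_
  }
  imp <- numeric()
  if (importance) {
    base <- acc$overall
    set.seed(seed)
    imp <- vapply(colnames(x), function(f) {
      drops <- vapply(seq_len(importanceRepeats), function(r) {
        xp <- x
        xp[, f] <- sample(xp[, f])
        pp <- .predictOne(model@kind, model@fit, xp, lev)
        base - mean(as.character(pp) == as.character(y))
      }, numeric(1))
      max(mean(drops), 0)
    }, numeric(1))
    if (sum(imp) > 0) imp <- imp / sum(imp)
  }
  new("ClassifierReport", kind = model@kind, task = task, confusion = conf,
      perClassAccuracy = acc$per_class, overallAccuracy = acc$overall,
      roc = roc, auc = auc, gini = gini, importance = imp)
}
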