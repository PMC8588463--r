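# Hand-written learners for families without an installed equivalent:
# a weighted-vote k-nearest-neighbour classifier (vote weighting is the
# class-imbalance device, which class::knn cannot express) and a univariate
# binary-split decision tree whose split variable is chosen by per-feature
# ANOVA F-tests -- an unbiased selection rule in the QUEST tradition, since
# the variable is picked before any split point is searched.

.knnModel <- function(x, y, weights, k = 3) {
  structure(list(x = x, y = y, w = weights, k = k), class = "drivewave_knn")
}

.knnScores <- function(model, newx) {
  # weighted votes per class for each row of newx
  tr <- model$x
  k <- model$k
  lev <- levels(model$y)
  d2 <- outer(rowSums(newx^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(newx)), rowSums(tr^2)) - 2 * newx %*% t(tr)
  votes <- matrix(0, nrow(newx), length(lev), dimnames = list(NULL, lev))
  nearest <- character(nrow(newx))
  for (i in seq_len(nrow(newx))) {
    nb <- order(d2[i, ])[seq_len(k)]
    for (j in nb) votes[i, as.character(model$y[j])] <-
        votes[i, as.character(model$y[j])] + model$w[[as.character(model$y[j])]]
    nearest[i] <- as.character(model$y[nb[1]])
  }
  list(votes = votes / rowSums(votes), nearest = nearest)
}

.knnPredict <- function(model, newx) {
  sc <- .knnScores(model, newx)
  lev <- colnames(sc$votes)
  pred <- character(nrow(newx))
  for (i in seq_len(nrow(newx))) {
    v <- sc$votes[i, ]
    top <- lev[v == max(v)]
    # ties broken by the nearest neighbour's class
    pred[i] <- if (length(top) == 1) top
               else if (sc$nearest[i] %in% top) sc$nearest[i] else top[1]
  }
  factor(pred, levels = lev)
}

# ---- univariate ANOVA-split tree -------------------------------------------

.anovaP <- function(x, g) {
  # one-way ANOVA p-value of x across groups g (>= 2 non-constant groups)
  if (sd(x) == 0) return(1)
  fit <- tryCatch(stats::oneway.test(x ~ g, var.equal = TRUE),
                  error = function(e) NULL)
  if (is.null(fit) || is.na(fit$p.value)) 1 else fit$p.value
}

.weightedMajority <- function(y, w) {
  tab <- tapply(w[as.character(y)], y, sum, default = 0)
  names(tab)[which.max(tab)]
}

.growUnivariateTree <- function(x, y, w, depth, maxDepth, minNode, alpha) {
  lev <- levels(y)
  node <- list(n = length(y),
               prediction = .weightedMajority(y, w),
               prob = prop.table(tapply(w[as.character(y)], y, sum,
                                        default = 0)))
  if (depth >= maxDepth || length(y) < minNode || length(unique(y)) == 1)
    return(node)
  # unbiased variable selection: test every feature, pick the smallest p
  ps <- apply(x, 2, .anovaP, g = y)
  if (min(ps) > alpha) return(node)
  v <- names(which.min(ps))
  # split point: midpoint of the two extreme class means along v
  cm <- tapply(x[, v], y, mean)
  cm <- cm[!is.na(cm)]
  if (length(cm) < 2) return(node)
  if (length(cm) == 2) {
    cut <- mean(cm)
  } else {
    # merge classes into two super-groups around the largest mean gap
    s <- sort(cm)
    gap <- which.max(diff(s))
    cut <- (s[gap] + s[gap + 1]) / 2
  }
  left <- x[, v] <= cut
  if (!any(left) || all(left)) return(node)
  node$split <- list(var = v, cut = cut)
  node$left <- .growUnivariateTree(x[left, , drop = FALSE], droplevels(y[left]),
                                   w, depth + 1, maxDepth, minNode, alpha)
  node$right <- .growUnivariateTree(x[!left, , drop = FALSE],
                                    droplevels(y[!left]),
                                    w, depth + 1, maxDepth, minNode, alpha)
  node
}

.univariateTree <- function(x, y, weights, maxDepth = 8, minNode = 10,
                            alpha = 0.05) {
  structure(list(root = .growUnivariateTree(x, y, weights, 0, maxDepth,
                                            minNode, alpha),
                 levels = levels(y)),
            class = "drivewave_utree")
}

.utreeProb <- function(model, newx) {
  lev <- model$levels
  out <- matrix(0, nrow(newx), length(lev), dimnames = list(NULL, lev))
  walk <- function(node, idx) {
    if (is.null(node$split) || !length(idx)) {
      p <- setNames(rep(0, length(lev)), lev)
      p[names(node$prob)] <- node$prob
      out[idx, ] <<- matrix(p, length(idx), length(lev), byrow = TRUE)
      return(invisible())
    }
    left <- newx[idx, node$split$var] <= node$split$cut
    walk(node$left, idx[left])
    walk(node$right, idx[!left])
  }
  walk(model$root, seq_len(nrow(newx)))
  out
}

.utreePredict <- function(model, newx) {
  pr <- .utreeProb(model, newx)
  factor(colnames(pr)[max.col(pr, ties.method = "first")],
         levels = model$levels)
}
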