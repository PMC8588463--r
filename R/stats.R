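# Descriptive and comparative statistics over the feature table: per-state
# summaries with 95% confidence intervals, paired subject-level comparisons
# between states, and band-vs-band ordinary least squares regressions.

.featureVector <- function(ft, feature) {
  mat <- SummarizedExperiment::assay(ft, "features")
  if (!feature %in% rownames(mat))
    stop(sprintf("unknown feature '%s'", feature))
  mat[feature, ]
}

#' Per-state descriptive statistics
#'
#' Mean, SD and the t-based 95% confidence interval
#' (mean +/- t[0.975, n-1] SD / sqrt(n)) of one feature per state. The CI is
#' undefined (NA) for a single-epoch state.
#'
#' @param ft a [FeatureTable-class].
#' @param feature feature (row) name.
#' @param conf confidence level.
#' @return data.frame with columns `state`, `n`, `mean`, `sd`, `ci_lo`,
#'   `ci_hi`.
#' @export
describeByState <- function(ft, feature, conf = 0.95) {
  x <- .featureVector(ft, feature)
  st <- SummarizedExperiment::colData(ft)$state
  out <- do.call(rbind, lapply(unique(st), function(s) {
    v <- x[st == s]
    v <- v[!is.na(v)]
    n <- length(v)
    m <- mean(v)
    sdev <- if (n > 1) sd(v) else NA_real_
    half <- if (n > 1) qt(1 - (1 - conf) / 2, n - 1) * sdev / sqrt(n)
            else NA_real_
    data.frame(state = s, n = n, mean = m, sd = sdev,
               ci_lo = m - half, ci_hi = m + half)
  }))
  rownames(out) <- NULL
  out
}

#' Paired comparison of one feature between two states
#'
#' Epoch counts are unbalanced across states, so epochs are first aggregated
#' to one value per subject per state (subject means); subjects present in
#' both states are then compared with a paired two-sided t-test. The relative
#' difference is `(mean_b - mean_a) / mean_a` computed from the two state
#' means of the paired subjects.
#'
#' @param ft a [FeatureTable-class].
#' @param feature feature (row) name.
#' @param stateA baseline state.
#' @param stateB comparison state.
#' @return data.frame (one row): feature, states, per-state means and SDs,
#'   `rel_diff`, `t`, `df`, `p`, `significant` (p < 0.05), `n_pairs`.
#' @export
pairedCompare <- function(ft, feature, stateA = "resting",
                          stateB = "city_roadway") {
  x <- .featureVector(ft, feature)
  cd <- SummarizedExperiment::colData(ft)
  subjMean <- function(s) {
    keep <- cd$state == s & !is.na(x)
    tapply(x[keep], cd$subject[keep], mean)
  }
  a <- subjMean(stateA)
  b <- subjMean(stateB)
  common <- intersect(names(a), names(b))
  if (length(common) < length(a) || length(common) < length(b))
    warning("subjects without both states dropped from the pairing")
  if (length(common) < 2) stop("need >= 2 paired subjects")
  a <- a[common]
  b <- b[common]
  d <- b - a
  if (sd(d) == 0) {
    warning("zero variance of paired differences; degenerate t-test")
    tt <- list(statistic = if (all(d == 0)) 0 else sign(mean(d)) * Inf,
               parameter = length(d) - 1,
               p.value = if (all(d == 0)) 1 else 0)
  } else {
    tt <- t.test(b, a, paired = TRUE)
  }
  data.frame(feature = feature, state_a = stateA, state_b = stateB,
             mean_a = mean(a), sd_a = sd(a), mean_b = mean(b), sd_b = sd(b),
             rel_diff = (mean(b) - mean(a)) / mean(a),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, significant = tt$p.value < 0.05,
             n_pairs = length(common))
}

#' Band-vs-band linear regression
#'
#' Ordinary least squares of feature `y` on feature `x`, optionally within
#' one state. Reports slope, intercept, Pearson r, R-squared (= r^2 for a
#' simple regression) and the slope's p-value. The slope and the correlation
#' coefficient are reported separately and never conflated.
#'
#' @param ft a [FeatureTable-class].
#' @param x,y feature (row) names.
#' @param state optional state label to subset on.
#' @return data.frame (one row): x, y, state, `n`, `slope`, `intercept`,
#'   `r`, `r_squared`, `p`.
#' @export
regressBands <- function(ft, x, y, state = NULL) {
  xv <- .featureVector(ft, x)
  yv <- .featureVector(ft, y)
  st <- SummarizedExperiment::colData(ft)$state
  keep <- !is.na(xv) & !is.na(yv)
  if (!is.null(state)) keep <- keep & st == state
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 3) stop("need >= 3 points for regression")
  if (sd(xv) == 0) stop("zero variance in x: slope undefined")
  fit <- lm(yv ~ xv)
  sm <- summary(fit)
  data.frame(x = x, y = y, state = state %||% "all", n = length(xv),
             slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
             r = stats::cor(xv, yv), r_squared = sm$r.squared,
             p = sm$coefficients[2, 4])
}

#' Published-style statistics report
#'
#' Convenience wrapper producing the global band relative-power and DAR/DTR
#' summary rows (mean, SD, baseline-relative difference, paired p) for both
#' driving states against the resting baseline.
#'
#' @param ft a [FeatureTable-class] containing all three states.
#' @return data.frame, one row per feature x driving state.
#' @export
statsReport <- function(ft) {
  feats <- c(paste("global", .BANDS, "relpow", sep = "_"),
             as.vector(outer(.EEG_CHANNELS, c("dar", "dtr"), paste,
                             sep = "_")))
  feats <- intersect(feats, rownames(SummarizedExperiment::assay(ft)))
  do.call(rbind, lapply(feats, function(f) {
    do.call(rbind, lapply(c("city_roadway", "expressway"), function(s)
      pairedCompare(ft, f, "resting", s)))
  }))
}
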