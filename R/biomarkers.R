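# Composite biomarkers on top of the spectral features: per-subject resting
# baseline, baseline-relative change, frontal asymmetry, delta-alpha and
# delta-theta ratios, and assembly of the 149-column epoch feature table.

#' The 149 feature column names
#'
#' Deterministic naming scheme
#' `{channel|lobe}_{band}_{relpow|medfreq|meanfreq|edgefreq|peakfreq}` for
#' band features, `{channel}_{dar|dtr}` for delta ratios,
#' `{channel}_total_pow` for total power, and a `d_` prefix for change
#' relative to the subject's resting baseline. Column order is stable, so
#' tables are reproducible model inputs.
#'
#' @return character vector of length 149.
#' @examples
#' length(featureColumns())  # 149
#' @export
featureColumns <- function() {
  perChan <- as.vector(t(outer(
    .EEG_CHANNELS,
    as.vector(t(outer(.BANDS,
                      c("relpow", "medfreq", "meanfreq", "edgefreq",
                        "peakfreq"), paste, sep = "_"))),
    paste, sep = "_")))
  globalRel <- paste("global", .BANDS, "relpow", sep = "_")
  lobeRel <- as.vector(t(outer(c("frontal", "occipital"), .BANDS,
                               function(a, b) paste(a, b, "relpow", sep = "_"))))
  dLobeRel <- paste0("d_", lobeRel)
  ratios <- as.vector(t(outer(.EEG_CHANNELS, c("dar", "dtr"), paste,
                              sep = "_")))
  dRatios <- paste0("d_", ratios)
  totals <- paste0(.EEG_CHANNELS, "_total_pow")
  dTotals <- paste0("d_", totals)
  c(perChan, globalRel, lobeRel, dLobeRel, ratios, dRatios, totals, dTotals)
}

# base features that get a baseline-relative d_ companion
.deltaBaseColumns <- function() {
  c(as.vector(t(outer(c("frontal", "occipital"), .BANDS,
                      function(a, b) paste(a, b, "relpow", sep = "_")))),
    as.vector(t(outer(.EEG_CHANNELS, c("dar", "dtr"), paste, sep = "_"))),
    paste0(.EEG_CHANNELS, "_total_pow"))
}

#' Per-subject resting baseline
#'
#' Arithmetic mean of every numeric feature over each subject's resting
#' epochs. The baseline is per subject, so baseline-relative features remain
#' computable for a new subject at inference time.
#'
#' @param features data.frame from [epochSpectralFeatures()] (or any table
#'   with `subject`, `state` and numeric feature columns).
#' @param restingLabel the state label identifying baseline epochs.
#' @return data.frame, one row per subject with a resting epoch; attribute
#'   `"n_epochs"` gives the per-subject epoch counts used.
#' @export
restingBaseline <- function(features, restingLabel = "resting") {
  rest <- features[features$state == restingLabel, , drop = FALSE]
  if (!nrow(rest)) stop("no resting epochs: baseline unavailable")
  num <- vapply(rest, is.numeric, logical(1))
  num[names(num) == "epoch"] <- FALSE
  subj <- unique(rest$subject)
  out <- do.call(rbind, lapply(subj, function(s) {
    sub <- rest[rest$subject == s, num, drop = FALSE]
    as.data.frame(lapply(sub, mean))
  }))
  out <- data.frame(subject = subj, out, check.names = FALSE)
  attr(out, "n_epochs") <- setNames(
    vapply(subj, function(s) sum(rest$subject == s), integer(1)), subj)
  out
}

#' Change relative to baseline
#'
#' `(value - baseline) / baseline`, stored as a fraction (multiply by 100
#' only for display). A zero baseline yields a missing value with a warning.
#'
#' @param value,baseline numeric vectors (recycled).
#' @return numeric vector of fractions.
#' @examples
#' relativeChange(0.133, 0.124)  # 0.0726
#' @export
relativeChange <- function(value, baseline) {
  out <- (value - baseline) / baseline
  zero <- !is.na(baseline) & baseline == 0
  if (any(zero)) {
    warning("zero baseline: relative change undefined, set to NA")
    out[zero] <- NA_real_
  }
  out
}

#' Hemispheric asymmetry index
#'
#' `(right - left) / (right + left)`, in `[-1, 1]`, computed per band for the
#' frontal electrode pair (Fp2 right, Fp1 left). Antisymmetric under swapping
#' the hemispheres. Returns `NA` when both inputs are zero.
#'
#' @param eRight,eLeft non-negative band powers (or relative powers).
#' @return numeric asymmetry index.
#' @examples
#' asymmetryIndex(0.3, 0.1)  # 0.5
#' @export
asymmetryIndex <- function(eRight, eLeft) {
  tot <- eRight + eLeft
  out <- (eRight - eLeft) / tot
  out[!is.na(tot) & tot == 0] <- NA_real_
  out
}

#' Delta-alpha and delta-theta ratios
#'
#' DAR = delta / alpha and DTR = delta / theta. Identical whether computed
#' from relative or absolute band powers (the common denominator cancels).
#' Zero denominators yield missing values.
#'
#' @param eDelta,eTheta,eAlpha band (relative) powers.
#' @return named numeric vector `c(dar = , dtr = )` for scalar input, or a
#'   two-column matrix for vector input.
#' @examples
#' deltaRatios(0.4, 0.4, 0.1)  # dar 4, dtr 1
#' @export
deltaRatios <- function(eDelta, eTheta, eAlpha) {
  dar <- ifelse(!is.na(eAlpha) & eAlpha > 0, eDelta / eAlpha, NA_real_)
  dtr <- ifelse(!is.na(eTheta) & eTheta > 0, eDelta / eTheta, NA_real_)
  if (length(eDelta) == 1L) c(dar = dar, dtr = dtr)
  else cbind(dar = dar, dtr = dtr)
}

#' Assemble the 149-column epoch feature table
#'
#' Combines the base spectral features with their baseline-relative (`d_`)
#' companions into a [FeatureTable-class] (a `SummarizedExperiment` with a
#' features x epochs assay and `subject`/`state` column data). Baselines are
#' per subject; a subject without resting epochs gets `NA` in every `d_`
#' column (missingness propagates only into dependent columns).
#'
#' @param spectral data.frame from [epochSpectralFeatures()].
#' @param baselines optional data.frame from [restingBaseline()]; computed
#'   from `spectral`'s resting rows when `NULL`.
#' @return a [FeatureTable-class] with exactly `length(featureColumns())`
#'   rows (features).
#' @export
buildFeatureTable <- function(spectral, baselines = NULL) {
  cols <- featureColumns()
  base <- setdiff(cols, grep("^d_", cols, value = TRUE))
  missingBase <- setdiff(base, names(spectral))
  if (length(missingBase))
    stop("spectral features missing columns: ",
         paste(missingBase, collapse = ", "))
  if (is.null(baselines)) baselines <- restingBaseline(spectral)
  n <- nrow(spectral)
  mat <- matrix(NA_real_, length(cols), n,
                dimnames = list(cols, paste0("epoch", seq_len(n))))
  for (cc in base) mat[cc, ] <- spectral[[cc]]
  bmap <- match(spectral$subject, baselines$subject)
  for (cc in .deltaBaseColumns()) {
    bl <- baselines[[cc]][bmap]
    mat[paste0("d_", cc), ] <- relativeChange(spectral[[cc]], bl)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(features = mat),
    colData = S4Vectors::DataFrame(subject = spectral$subject,
                                   state = spectral$state)) |>
    methods::as("FeatureTable")
}

#' Feature table as a data.frame
#'
#' Epoch-per-row view of a [FeatureTable-class]: `subject`, `state`, then the
#' 149 feature columns.
#'
#' @param ft a [FeatureTable-class].
#' @return data.frame with one row per epoch.
#' @export
featureFrame <- function(ft) {
  stopifnot(is(ft, "FeatureTable"))
  mat <- SummarizedExperiment::assay(ft, "features")
  cd <- SummarizedExperiment::colData(ft)
  data.frame(subject = cd$subject, state = cd$state, t(mat),
             check.names = FALSE)
}
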