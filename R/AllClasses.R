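NULL

.BANDS <- c("delta", "theta", "alpha", "beta", "gamma")
.EEG_CHANNELS <- c("Fp1", "Fp2", "O1", "O2")
.STATES <- c("resting", "city_roadway", "expressway")

#' Frequency band scheme
#'
#' Contiguous, non-overlapping EEG frequency bands under the half-open
#' `[low, high)` convention, tiling the total analysis range. The default
#' scheme is delta 0.5--4, theta 4--8, alpha 8--13, beta 13--30 and gamma
#' 30--44 Hz, with the total range 0.5--44 Hz used as the denominator of
#' relative band power.
#'
#' @slot bands two-column matrix (low, high) in Hz, one row per band,
#'   rownames are the band names.
#' @slot totalRange length-2 numeric, total analysis range in Hz.
#' @exportClass BandScheme
setClass("BandScheme",
  representation(bands = "matrix", totalRange = "numeric"))

setValidity("BandScheme", function(object) {
  b <- object@bands
  if (ncol(b) != 2L || is.null(rownames(b)))
    return("bands must be a named two-column (low, high) matrix")
  if (any(b[, 1] >= b[, 2])) return("each band must have low < high")
  o <- order(b[, 1])
  bo <- b[o, , drop = FALSE]
  if (nrow(bo) > 1 && any(abs(bo[-nrow(bo), 2] - bo[-1, 1]) > 1e-9))
    return("bands must be contiguous and non-overlapping")
  if (abs(bo[1, 1] - object@totalRange[1]) > 1e-9 ||
      abs(bo[nrow(bo), 2] - object@totalRange[2]) > 1e-9)
    return("bands must tile totalRange exactly")
  TRUE
})

#' @describeIn BandScheme constructor; defaults to the five-band EEG scheme.
#' @param bands named two-column matrix of band edges in Hz.
#' @return a `BandScheme`.
#' @examples
#' defaultBandScheme()
#' @export
defaultBandScheme <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- rbind(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                   beta = c(13, 30), gamma = c(30, 44))
    colnames(bands) <- c("low", "high")
  }
  new("BandScheme", bands = bands,
      totalRange = c(min(bands[, 1]), max(bands[, 2])))
}

#' Per-state synthesis specification
#'
#' Describes the spectral composition of one neurological state for the
#' synthetic EEG generator: target mean and standard deviation of each band's
#' relative power across 10-s epochs, an optional right-minus-left frontal
#' asymmetry offset per band, the total signal power, and the cohort layout
#' (subjects, epochs per subject after the initial trim).
#'
#' @slot state one of `"resting"`, `"city_roadway"`, `"expressway"`.
#' @slot bandRelMean named numeric, mean relative power per band; must be
#'   positive and is renormalized to sum to one.
#' @slot bandRelSD named numeric, between-epoch SD of relative power per band.
#' @slot asymmetryOffset named numeric, right-minus-left relative-power bias
#'   per band (default all zero).
#' @slot totalPower positive scalar, epoch signal variance in uV^2.
#' @slot nSubjects integer, number of subjects.
#' @slot epochsPerSubject integer, 10-s epochs per subject surviving the
#'   initial trim (segment duration = (epochsPerSubject + leadIn/10) x 10 s).
#' @exportClass StateSpec
setClass("StateSpec",
  representation(state = "character", bandRelMean = "numeric",
                 bandRelSD = "numeric", asymmetryOffset = "numeric",
                 totalPower = "numeric", nSubjects = "integer",
                 epochsPerSubject = "integer"))

setValidity("StateSpec", function(object) {
  m <- object@bandRelMean
  if (!identical(sort(names(m)), sort(.BANDS)))
    return("bandRelMean must be named with the five band names")
  if (any(m <= 0)) return("band relative-power means must all be positive")
  if (abs(sum(m / sum(m)) - 1) > 1e-9)
    return("band means must renormalize to sum to 1")
  if (any(object@bandRelSD < 0)) return("band SDs must be non-negative")
  if (object@totalPower <= 0) return("totalPower must be positive")
  if (object@nSubjects < 1L || object@epochsPerSubject < 1L)
    return("nSubjects and epochsPerSubject must be >= 1")
  TRUE
})

#' Multichannel raw recording
#'
#' A uniformly sampled multichannel biosignal recording. EEG channels carry
#' role `"eeg"`; auxiliary reference channels (electrooculogram,
#' electromyogram) carry roles `"eog"`/`"emg"`. Annotations mark
#' non-overlapping state segments with subject identifiers.
#'
#' @slot data numeric matrix, samples x channels, in uV.
#' @slot channels character, channel names (column order of `data`).
#' @slot roles character, per-channel role in `c("eeg","eog","emg")`.
#' @slot fs sampling rate in Hz.
#' @slot annotations data.frame with columns `onset`, `duration` (seconds),
#'   `state`, `subject`.
#' @exportClass RawRecording
setClass("RawRecording",
  representation(data = "matrix", channels = "character", roles = "character",
                 fs = "numeric", annotations = "data.frame"))

setValidity("RawRecording", function(object) {
  if (ncol(object@data) != length(object@channels))
    return("one data column per channel required")
  if (length(object@roles) != length(object@channels))
    return("one role per channel required")
  if (!all(object@roles %in% c("eeg", "eog", "emg")))
    return("roles must be eeg, eog or emg")
  if (object@fs <= 0) return("fs must be positive")
  a <- object@annotations
  need <- c("onset", "duration", "state", "subject")
  if (!all(need %in% names(a)))
    return("annotations need onset, duration, state, subject")
  if (nrow(a)) {
    if (any(a$onset < 0) || any(a$duration <= 0))
      return("annotation onsets must be >= 0 and durations > 0")
    dur <- nrow(object@data) / object@fs
    if (any(a$onset + a$duration > dur + 1e-6))
      return("annotations must lie within the recording")
    o <- order(a$onset)
    if (nrow(a) > 1 &&
        any(a$onset[o][-1] < (a$onset + a$duration)[o][-nrow(a)] - 1e-9))
      return("annotations must not overlap")
  }
  TRUE
})

#' @param data samples x channels numeric matrix (uV).
#' @param channels channel names.
#' @param roles per-channel roles (`"eeg"`, `"eog"`, `"emg"`).
#' @param fs sampling rate (Hz).
#' @param annotations data.frame of state segments (onset, duration, state,
#'   subject).
#' @return a `RawRecording`.
#' @describeIn RawRecording constructor.
#' @export
rawRecording <- function(data, channels, roles, fs,
                         annotations = data.frame(onset = numeric(),
                                                  duration = numeric(),
                                                  state = character(),
                                                  subject = character())) {
  colnames(data) <- channels
  new("RawRecording", data = as.matrix(data), channels = channels,
      roles = roles, fs = fs, annotations = annotations)
}

#' Preprocessing configuration
#'
#' Parameters of the cleaning chain: power-line notch frequency, target
#' sampling rate after anti-aliased downsampling, zero-phase band-pass edges,
#' seconds trimmed from the start of every state segment, epoch width, and the
#' reference-correlation threshold for ICA component rejection.
#'
#' @slot notchHz power-line frequency (Hz), 0 disables the notch.
#' @slot targetFs target sampling rate (Hz).
#' @slot bandpass length-2 numeric band-pass edges (Hz).
#' @slot dropInitial seconds removed from the start of each segment.
#' @slot epochSeconds epoch width (s).
#' @slot icaEnabled logical.
#' @slot icaThreshold absolute Pearson correlation above which an independent
#'   component is rejected, in (0, 1].
#' @exportClass PreprocessConfig
setClass("PreprocessConfig",
  representation(notchHz = "numeric", targetFs = "numeric",
                 bandpass = "numeric", dropInitial = "numeric",
                 epochSeconds = "numeric", icaEnabled = "logical",
                 icaThreshold = "numeric"))

setValidity("PreprocessConfig", function(object) {
  bp <- object@bandpass
  if (length(bp) != 2L || bp[1] >= bp[2])
    return("bandpass must be (low, high) with low < high")
  if (bp[2] >= object@targetFs / 2)
    return("bandpass high edge must be below targetFs/2")
  if (object@epochSeconds <= 0) return("epochSeconds must be positive")
  if (object@dropInitial < 0) return("dropInitial must be >= 0")
  if (object@icaThreshold <= 0 || object@icaThreshold > 1)
    return("icaThreshold must be in (0, 1]")
  TRUE
})

#' @describeIn PreprocessConfig constructor with study defaults (60 Hz notch,
#'   250 Hz, 0.5--44 Hz, 30 s trim, 10 s epochs, ICA threshold 0.7).
#' @param notchHz,targetFs,bandpass,dropInitial,epochSeconds,icaEnabled,icaThreshold
#'   see slots.
#' @return a `PreprocessConfig`.
#' @export
preprocessConfig <- function(notchHz = 60, targetFs = 250,
                             bandpass = c(0.5, 44), dropInitial = 30,
                             epochSeconds = 10, icaEnabled = TRUE,
                             icaThreshold = 0.7) {
  new("PreprocessConfig", notchHz = notchHz, targetFs = targetFs,
      bandpass = bandpass, dropInitial = dropInitial,
      epochSeconds = epochSeconds, icaEnabled = icaEnabled,
      icaThreshold = icaThreshold)
}

#' Epoched recording
#'
#' Fixed-width, non-overlapping epochs cut from the annotated state segments
#' of a preprocessed recording.
#'
#' @slot epochs numeric array, epoch x channel x sample.
#' @slot channels channel names (EEG only).
#' @slot fs sampling rate (Hz).
#' @slot state state label per epoch.
#' @slot subject subject identifier per epoch.
#' @exportClass EpochedRecording
setClass("EpochedRecording",
  representation(epochs = "array", channels = "character", fs = "numeric",
                 state = "character", subject = "character"))

setValidity("EpochedRecording", function(object) {
  d <- dim(object@epochs)
  if (length(d) != 3L) return("epochs must be a 3-d array")
  if (d[2] != length(object@channels))
    return("second dimension must match channels")
  if (d[1] != length(object@state) || d[1] != length(object@subject))
    return("state and subject must have one entry per epoch")
  if (anyNA(object@epochs)) return("epochs must not contain NA")
  TRUE
})

#' Power spectral density estimate
#'
#' One-sided Welch power spectral density for one epoch, per channel.
#'
#' @slot freqs frequency grid (Hz).
#' @slot power channels x frequencies density matrix (uV^2/Hz).
#' @slot channels channel names.
#' @exportClass PSDEstimate
setClass("PSDEstimate",
  representation(freqs = "numeric", power = "matrix", channels = "character"))

setValidity("PSDEstimate", function(object) {
  if (ncol(object@power) != length(object@freqs))
    return("power must have one column per frequency")
  if (nrow(object@power) != length(object@channels))
    return("power must have one row per channel")
  if (any(object@power < -1e-12)) return("power must be non-negative")
  TRUE
})

#' Epoch-by-feature table
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single `"features"`
#' assay holds the 149 named spectral/biomarker features (rows) for every
#' 10-s epoch (columns); `colData` carries the epoch's `subject` and `state`.
#'
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

#' Fitted classifier
#'
#' A classifier trained on standardized (distance/kernel families) or raw
#' (tree families) features with inverse-frequency class weights, plus its
#' stratified k-fold cross-validation accuracy.
#'
#' @slot kind one of `"knn"`, `"lda"`, `"svm"`, `"tree_gain_ratio"`,
#'   `"tree_univariate"`.
#' @slot fit fitted model object (family specific).
#' @slot center,scale training-partition standardization (empty for trees).
#' @slot featureNames features the model consumes, in order.
#' @slot classLevels class labels.
#' @slot classWeights inverse-frequency class weights used for training.
#' @slot cvAccuracy mean cross-validated accuracy.
#' @slot foldAccuracy per-fold accuracies.
#' @slot seed integer seed that fixed fold assignment.
#' @exportClass ClassifierFit
setClass("ClassifierFit",
  representation(kind = "character", fit = "ANY", center = "numeric",
                 scale = "numeric", featureNames = "character",
                 classLevels = "character", classWeights = "numeric",
                 cvAccuracy = "numeric", foldAccuracy = "numeric",
                 seed = "integer"))

#' Classification report
#'
#' Confusion matrix and derived performance measures for a fitted classifier
#' evaluated on a held-out table: per-class and overall accuracy, and (for
#' binary tasks) ROC points, trapezoid AUC and Gini = 2 AUC - 1, plus
#' permutation predictor importances.
#'
#' @slot kind model family.
#' @slot task `"multiclass"` or `"<a>_vs_<b>"`.
#' @slot confusion actual x predicted count matrix.
#' @slot perClassAccuracy diagonal / row sum.
#' @slot overallAccuracy trace / total.
#' @slot roc data.frame with columns `fpr`, `tpr` (binary tasks; else empty).
#' @slot auc trapezoid area under the ROC (NA for multiclass).
#' @slot gini 2 * AUC - 1 (NA for multiclass).
#' @slot importance named numeric permutation importances (may be empty).
#' @exportClass ClassifierReport
setClass("ClassifierReport",
  representation(kind = "character", task = "character",
                 confusion = "matrix", perClassAccuracy = "numeric",
                 overallAccuracy = "numeric", roc = "data.frame",
                 auc = "numeric", gini = "numeric", importance = "numeric"))

setValidity("ClassifierReport", function(object) {
  m <- object@confusion
  if (nrow(m) != ncol(m)) return("confusion matrix must be square")
  if (any(m < 0) || any(abs(m - round(m)) > 1e-9))
    return("confusion matrix entries must be non-negative integers")
  TRUE
})
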