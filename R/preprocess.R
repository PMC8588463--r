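# Cleaning chain: power-line notch -> anti-aliased downsampling ->
# reference-guided ICA (separate entry point) -> zero-phase band-pass.
# All IIR filters are Butterworth applied forward-backward (filtfilt), so no
# stage introduces phase distortion that would bias asymmetry features.

.filtfiltCols <- function(filt, x) {
  apply(x, 2, function(col) signal::filtfilt(filt, col))
}

.notch <- function(x, fs, notchHz, width = 2) {
  if (notchHz <= 0 || notchHz >= fs / 2) return(x)
  f <- signal::butter(2, c(notchHz - width / 2, notchHz + width / 2) / (fs / 2),
                      type = "stop")
  .filtfiltCols(f, x)
}

.decimateTo <- function(x, fs, targetFs) {
  if (fs == targetFs) return(x)
  r <- fs / targetFs
  if (abs(r - round(r)) > 1e-9)
    stop("sampling rate must be an integer multiple of targetFs")
  # anti-aliasing low-pass at 0.8 x Nyquist of the target rate
  f <- signal::butter(6, 0.8 * (targetFs / 2) / (fs / 2), type = "low")
  y <- .filtfiltCols(f, x)
  y[seq(1, nrow(y), by = round(r)), , drop = FALSE]
}

.bandpass <- function(x, fs, edges, order = 4) {
  f <- signal::butter(order, edges / (fs / 2), type = "pass")
  .filtfiltCols(f, x)
}

#' Preprocess a raw recording
#'
#' Applies, in order: notch filter at the power-line frequency, anti-aliased
#' downsampling to the target rate, and a zero-phase band-pass. Channel order,
#' roles and annotations are preserved; the input is not modified.
#'
#' @param rec a [RawRecording-class]; `samplingRate(rec)` must be at least
#'   twice the band-pass high edge and the recording must be long enough to
#'   hold the initial trim plus one epoch.
#' @param cfg a [PreprocessConfig-class].
#' @return a new [RawRecording-class] at `cfg@targetFs`.
#' @examples
#' rec <- synthesizeRecording(defaultStateSpecs()$resting, seed = 1,
#'                            fs = 1000, leadIn = 0)
#' clean <- preprocessRecording(rec, preprocessConfig(dropInitial = 0))
#' @export
preprocessRecording <- function(rec, cfg = preprocessConfig()) {
  stopifnot(is(rec, "RawRecording"), is(cfg, "PreprocessConfig"))
  validObject(cfg)
  if (rec@fs < 2 * cfg@bandpass[2])
    stop(sprintf("sampling rate %g Hz is below twice the band-pass high edge",
                 rec@fs))
  if (nrow(rec@data) / rec@fs < cfg@dropInitial + cfg@epochSeconds)
    stop("recording shorter than dropInitial + one epoch")
  x <- .notch(rec@data, rec@fs, cfg@notchHz)
  x <- .decimateTo(x, rec@fs, cfg@targetFs)
  x <- .bandpass(x, cfg@targetFs, cfg@bandpass)
  out <- rawRecording(x, rec@channels, rec@roles, cfg@targetFs,
                      rec@annotations)
  attr(out, "targets") <- attr(rec, "targets")
  out
}

#' Signal-to-noise ratio of a disturbed epoch
#'
#' Mean power of the disturbed signal divided by mean power of the clean
#' reference measurement.
#'
#' @param disturbed,clean equal-length numeric vectors.
#' @return list with `ratio` (dimensionless) and `db` (10 log10 ratio).
#' @examples
#' estimateSNR(c(1, -1, 1, -1), c(1, -1, 1, -1))$ratio  # 1
#' @export
estimateSNR <- function(disturbed, clean) {
  if (length(disturbed) != length(clean))
    stop("disturbed and clean must have equal length")
  pc <- mean(clean^2)
  if (pc == 0) stop("clean signal has zero power")
  r <- mean(disturbed^2) / pc
  list(ratio = r, db = 10 * log10(r))
}

#' Cut annotated segments into fixed-width epochs
#'
#' For every annotated state segment, drops the first `cfg@dropInitial`
#' seconds, then cuts consecutive non-overlapping epochs of
#' `cfg@epochSeconds`, discarding any trailing partial epoch. Epochs inherit
#' the segment's state and subject labels. A segment too short to yield an
#' epoch contributes none, with a warning.
#'
#' @param rec a preprocessed [RawRecording-class] with annotations.
#' @param cfg a [PreprocessConfig-class].
#' @return an [EpochedRecording-class] over the EEG channels.
#' @export
segmentEpochs <- function(rec, cfg = preprocessConfig()) {
  stopifnot(is(rec, "RawRecording"))
  ann <- rec@annotations
  if (!nrow(ann)) stop("recording has no annotations to segment")
  fs <- rec@fs
  epN <- round(cfg@epochSeconds * fs)
  eegIdx <- which(rec@roles == "eeg")
  chans <- rec@channels[eegIdx]
  pieces <- list()
  state <- character()
  subject <- character()
  for (i in seq_len(nrow(ann))) {
    usable <- ann$duration[i] - cfg@dropInitial
    k <- max(floor(usable / cfg@epochSeconds), 0)
    if (k == 0) {
      warning(sprintf(
        "segment %d (%s/%s): %.1f s usable after trim, no epochs",
        i, ann$subject[i], ann$state[i], max(usable, 0)))
      next
    }
    start <- round((ann$onset[i] + cfg@dropInitial) * fs)
    for (j in seq_len(k)) {
      idx <- start + (j - 1) * epN + seq_len(epN)
      pieces[[length(pieces) + 1L]] <-
        t(rec@data[idx, eegIdx, drop = FALSE])
      state <- c(state, ann$state[i])
      subject <- c(subject, ann$subject[i])
    }
  }
  if (!length(pieces)) stop("no segment yielded any epoch")
  arr <- array(0, dim = c(length(pieces), length(chans), epN))
  for (i in seq_along(pieces)) arr[i, , ] <- pieces[[i]]
  new("EpochedRecording", epochs = arr, channels = chans, fs = fs,
      state = state, subject = subject)
}
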