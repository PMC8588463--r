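# Supporting engineering: recording readers/writers (long CSV and minimal
# EDF), a strict YAML pipeline configuration, and the end-to-end pipeline
# runner. Every artifact written to disk is stamped with the configuration
# hash, seed and package version.

#' Write a recording as long-format CSV
#'
#' Columns: `subject`, `channel`, `time_s`, `value_uV`, `state`. Time is
#' seconds from segment start; amplitudes are uV. Samples outside any
#' annotated segment are not written.
#'
#' @param rec a [RawRecording-class] with annotations.
#' @param path output file.
#' @param digits significant digits for amplitudes.
#' @return `path`, invisibly.
#' @export
writeRecordingCSV <- function(rec, path, digits = 6) {
  stopifnot(is(rec, "RawRecording"))
  ann <- rec@annotations
  if (!nrow(ann)) stop("recording has no annotations to write")
  fs <- rec@fs
  pieces <- lapply(seq_len(nrow(ann)), function(i) {
    idx <- round(ann$onset[i] * fs) + seq_len(round(ann$duration[i] * fs))
    do.call(rbind, lapply(seq_along(rec@channels), function(ch)
      data.frame(subject = ann$subject[i], channel = rec@channels[ch],
                 role = rec@roles[ch],
                 time_s = (seq_along(idx) - 1) / fs,
                 value_uV = signif(rec@data[idx, ch], digits),
                 state = ann$state[i])))
  })
  out <- do.call(rbind, pieces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# drivewave recording: fs_hz=%g time=s amplitude=uV",
                     fs), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Read a long-format CSV recording
#'
#' Inverse of [writeRecordingCSV()]. Validates that every channel carries the
#' same uniform time grid and that the required EEG channels are present.
#'
#' @param path CSV file written by [writeRecordingCSV()].
#' @param requiredChannels channels that must be present.
#' @return a [RawRecording-class].
#' @export
readRecordingCSV <- function(path, requiredChannels = .EEG_CHANNELS) {
  header <- readLines(path, n = 1)
  fs <- as.numeric(sub(".*fs_hz=([0-9.]+).*", "\\1", header))
  if (!startsWith(header, "#") || is.na(fs))
    stop("malformed header: expected '# drivewave recording: fs_hz=...'")
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("subject", "channel", "role", "time_s", "value_uV", "state")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("CSV missing required columns: ", paste(missing, collapse = ", "))
  chans <- unique(df$channel)
  missingCh <- setdiff(requiredChannels, chans)
  if (length(missingCh))
    stop("recording is missing required channels: ",
         paste(missingCh, collapse = ", "))
  roles <- vapply(chans, function(ch)
    df$role[df$channel == ch][1], character(1))
  segKey <- unique(df[, c("subject", "state")])
  segs <- vector("list", nrow(segKey))
  ann <- data.frame(onset = numeric(), duration = numeric(),
                    state = character(), subject = character())
  onset <- 0
  dt <- 1 / fs
  for (i in seq_len(nrow(segKey))) {
    sub <- df[df$subject == segKey$subject[i] & df$state == segKey$state[i], ]
    ts <- sort(unique(sub$time_s))
    m <- matrix(NA_real_, length(ts), length(chans),
                dimnames = list(NULL, chans))
    for (ch in chans) {
      v <- sub[sub$channel == ch, ]
      tsv <- sort(v$time_s)
      bad <- which(abs(diff(tsv) - dt) > dt * 1e-3)
      if (length(bad))
        stop(sprintf(
          "non-uniform timestamps for subject %s (%s), channel %s: first bad step after t=%g s",
          segKey$subject[i], segKey$state[i], ch, tsv[bad[1]]))
      if (nrow(v) != length(ts))
        stop(sprintf("channel %s has %d samples, expected %d (subject %s)",
                     ch, nrow(v), length(ts), segKey$subject[i]))
      m[, ch] <- v$value_uV[order(v$time_s)]
    }
    segs[[i]] <- m
    ann <- rbind(ann, data.frame(onset = onset, duration = length(ts) / fs,
                                 state = segKey$state[i],
                                 subject = segKey$subject[i]))
    onset <- onset + length(ts) / fs
  }
  rawRecording(do.call(rbind, segs), chans, unname(roles), fs, ann)
}

# ---- minimal EDF ------------------------------------------------------------
# Plain EDF: fixed ASCII header + 16-bit little-endian data records. One
# record per second. Annotations do not fit plain EDF, so they travel in a
# plain-text sidecar `<path>.annotations.csv` (documented, round-trip safe).

.edfPad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

#' Write a recording as EDF
#'
#' Minimal plain-EDF writer: 16-bit samples, one data record per second, the
#' recording truncated to whole seconds. State annotations are written to a
#' plain-text sidecar `<path>.annotations.csv` (plain EDF has no annotation
#' channel).
#'
#' @param rec a [RawRecording-class]; `samplingRate(rec)` must be an integer.
#' @param path output `.edf` file.
#' @return `path`, invisibly.
#' @export
writeRecordingEDF <- function(rec, path) {
  stopifnot(is(rec, "RawRecording"))
  fs <- rec@fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  ns <- length(rec@channels)
  nRec <- floor(nrow(rec@data) / fs)
  if (nRec < 1) stop("recording shorter than one EDF record (1 s)")
  dat <- rec@data[seq_len(nRec * fs), , drop = FALSE]
  physMax <- pmax(apply(abs(dat), 2, max), 1)
  digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    .edfPad("0", 8), .edfPad("synthetic subject", 80),
    .edfPad("drivewave synthetic recording", 80),
    "01.01.00", "00.00.00",
    .edfPad(256 * (ns + 1), 8), .edfPad("", 44),
    .edfPad(nRec, 8), .edfPad(1, 8), .edfPad(ns, 4)),
    con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, .edfPad, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  field(rec@channels, 16)
  field(rep("", ns), 80)                      # transducer
  field(rep("uV", ns), 8)
  field(sprintf("%.6g", -physMax), 8)
  field(sprintf("%.6g", physMax), 8)
  field(rep(-digMax - 1, ns), 8)
  field(rep(digMax, ns), 8)
  field(rep("", ns), 80)                      # prefiltering
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)
  for (r in seq_len(nRec)) {
    idx <- (r - 1) * fs + seq_len(fs)
    for (ch in seq_len(ns)) {
      dig <- round(dat[idx, ch] / physMax[ch] * digMax)
      writeBin(as.integer(pmin(pmax(dig, -digMax - 1), digMax)), con,
               size = 2, endian = "little")
    }
  }
  if (nrow(rec@annotations))
    utils::write.csv(rec@annotations, paste0(path, ".annotations.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads files produced by [writeRecordingEDF()] (plain EDF, identical
#' per-signal sampling rates). Annotations are restored from the
#' `<path>.annotations.csv` sidecar when present.
#'
#' @param path `.edf` file.
#' @param requiredChannels channels that must be present.
#' @param roles optional named channel roles; inferred from channel names
#'   (EOG/EMG prefixes) otherwise.
#' @return a [RawRecording-class].
#' @export
readRecordingEDF <- function(path, requiredChannels = .EEG_CHANNELS,
                             roles = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w))
  version <- rd(8)
  if (version != "0") stop("malformed EDF header: bad version field")
  rd(80); rd(80); rd(8); rd(8)
  headerBytes <- as.integer(rd(8))
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (anyNA(c(headerBytes, nRec, recDur, ns)))
    stop("malformed EDF header: non-numeric size fields")
  rdFields <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- rdFields(16)
  rdFields(80)
  rdFields(8)
  physMin <- as.numeric(rdFields(8))
  physMax <- as.numeric(rdFields(8))
  digMin <- as.numeric(rdFields(8))
  digMax <- as.numeric(rdFields(8))
  rdFields(80)
  spr <- as.integer(rdFields(8))
  rdFields(32)
  if (length(unique(spr)) != 1)
    stop("EDF reader supports one common sampling rate; found: ",
         paste(unique(spr), collapse = ", "))
  fs <- spr[1] / recDur
  missingCh <- setdiff(requiredChannels, labels)
  if (length(missingCh))
    stop("EDF is missing required channels: ",
         paste(missingCh, collapse = ", "))
  dat <- matrix(0, nRec * spr[1], ns, dimnames = list(NULL, labels))
  for (r in seq_len(nRec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      phys <- physMin[ch] + (dig - digMin[ch]) / (digMax[ch] - digMin[ch]) *
        (physMax[ch] - physMin[ch])
      dat[(r - 1) * spr[ch] + seq_len(spr[ch]), ch] <- phys
    }
  }
  if (is.null(roles))
    roles <- ifelse(grepl("^EOG", labels, ignore.case = TRUE), "eog",
                    ifelse(grepl("^EMG", labels, ignore.case = TRUE), "emg",
                           "eeg"))
  sidecar <- paste0(path, ".annotations.csv")
  ann <- if (file.exists(sidecar)) utils::read.csv(sidecar) else
    data.frame(onset = numeric(), duration = numeric(), state = character(),
               subject = character())
  rawRecording(dat, labels, roles, fs, ann)
}

#' Read a recording in either supported format
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"`; inferred from the extension by default.
#' @param ... passed to the format reader.
#' @return a [RawRecording-class].
#' @export
readRecording <- function(path, format = c("auto", "csv", "edf"), ...) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  switch(format, csv = readRecordingCSV(path, ...),
         edf = readRecordingEDF(path, ...))
}

# ---- pipeline configuration -------------------------------------------------

.defaultConfigList <- function() {
  list(
    synthesis = list(seed = 1L, fs = 1000, total_power_uV2 = 100,
                     n_subjects = 17L,
                     epochs_per_subject = list(resting = 3L,
                                               city_roadway = 27L,
                                               expressway = 18L),
                     artifacts = list(blink_rate_hz = 0, emg_burst_rate_hz = 0,
                                      line_amp_uV = 0)),
    preprocess = list(notch_hz = 60, target_fs = 250,
                      bandpass = c(0.5, 44), drop_initial_s = 30,
                      epoch_s = 10, ica_enabled = FALSE,
                      ica_correlation_threshold = 0.7),
    spectra = list(segment_s = 2, overlap = 0.5),
    training = list(enabled = TRUE, models = c("knn", "lda", "svm"),
                    cv_k = 10, repeats = 1,
                    n_train_subjects = 12L, task = "multiclass",
                    importance_threshold = 0.95),
    paths = list(out_dir = "drivewave_out"))
}

.checkKeys <- function(cfg, template, path = "") {
  extra <- setdiff(names(cfg), names(template))
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "))
  for (k in names(cfg))
    if (is.list(template[[k]]) && !is.null(names(template[[k]])) &&
        k != "epochs_per_subject")
      .checkKeys(cfg[[k]], template[[k]], paste0(path, k, "."))
}

#' Read and validate a pipeline configuration
#'
#' Loads a single YAML document, rejects unknown keys, and merges it over the
#' package defaults.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return named configuration list with attribute `"hash"`.
#' @export
readPipelineConfig <- function(path = NULL) {
  base <- .defaultConfigList()
  if (!is.null(path)) {
    cfg <- yaml::read_yaml(path)
    .checkKeys(cfg, base)
    base <- utils::modifyList(base, cfg)
  }
  attr(base, "hash") <- rlang::hash(base)
  base
}

#' @rdname readPipelineConfig
#' @export
defaultPipelineConfig <- function() readPipelineConfig(NULL)

.provenance <- function(cfg)
  sprintf("# drivewave %s | config_hash=%s | seed=%s",
          as.character(utils::packageVersion("drivewave")),
          attr(cfg, "hash") %||% rlang::hash(cfg),
          cfg$synthesis$seed)

.logStage <- function(stage, msg)
  message(sprintf("[%s] %s | %s", format(Sys.time(), "%H:%M:%S"), stage, msg))

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> features -> biomarkers -> stats ->
#' train in order, writing each artifact (provenance-stamped CSV/JSON) under
#' the configured output directory. Rerunning with an identical
#' configuration reproduces identical feature tables. With training disabled
#' the run stops successfully after the statistics stage.
#'
#' @param cfg configuration list from [readPipelineConfig()].
#' @param outDir output directory (overrides `cfg$paths$out_dir`).
#' @return invisible list with the feature table, statistics report and any
#'   classifier reports.
#' @export
runPipeline <- function(cfg = defaultPipelineConfig(), outDir = NULL) {
  outDir <- outDir %||% cfg$paths$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  prov <- .provenance(cfg)
  sy <- cfg$synthesis

  .logStage("simulate", sprintf("seed=%d fs=%g", sy$seed, sy$fs))
  specs <- defaultStateSpecs()
  for (st in names(specs)) {
    specs[[st]]@nSubjects <- as.integer(sy$n_subjects)
    specs[[st]]@epochsPerSubject <- as.integer(sy$epochs_per_subject[[st]])
    specs[[st]]@totalPower <- sy$total_power_uV2
  }
  pp <- cfg$preprocess
  pcfg <- preprocessConfig(pp$notch_hz, pp$target_fs,
                           as.numeric(pp$bandpass), pp$drop_initial_s,
                           pp$epoch_s, pp$ica_enabled,
                           pp$ica_correlation_threshold)
  rec <- synthesizeCohort(specs, seed = sy$seed, fs = sy$fs,
                          leadIn = pp$drop_initial_s)
  art <- sy$artifacts
  hasArt <- art$blink_rate_hz > 0 || art$emg_burst_rate_hz > 0 ||
    art$line_amp_uV > 0
  if (hasArt)
    rec <- injectArtifacts(rec, art$blink_rate_hz, art$emg_burst_rate_hz,
                           art$line_amp_uV, seed = sy$seed)$recording

  .logStage("preprocess", sprintf("notch=%g target_fs=%g", pp$notch_hz,
                                  pp$target_fs))
  clean <- preprocessRecording(rec, pcfg)
  if (pp$ica_enabled && any(clean@roles != "eeg"))
    clean <- removeArtifactsICA(clean, cfg = pcfg)
  ep <- segmentEpochs(clean, pcfg)

  .logStage("features", sprintf("%d epochs", nEpochs(ep)))
  spc <- epochSpectralFeatures(ep, segmentSeconds = cfg$spectra$segment_s,
                               overlap = cfg$spectra$overlap)
  ft <- buildFeatureTable(spc)
  featPath <- file.path(outDir, "features.csv")
  con <- file(featPath, "w")
  writeLines(prov, con)
  utils::write.csv(
    cbind(featureFrame(ft)[, 1:2],
          signif(featureFrame(ft)[, -(1:2)], 6)), con, row.names = FALSE)
  close(con)

  .logStage("stats", "per-state summaries and paired comparisons")
  rep <- statsReport(ft)
  con <- file(file.path(outDir, "stats_report.csv"), "w")
  writeLines(prov, con)
  utils::write.csv(rep, con, row.names = FALSE)
  close(con)

  reports <- list()
  tr <- cfg$training
  if (isTRUE(tr$enabled)) {
    .logStage("train", paste(tr$models, collapse = ","))
    subj <- unique(SummarizedExperiment::colData(ft)$subject)
    trainIds <- subj[seq_len(tr$n_train_subjects)]
    testIds <- setdiff(subj, trainIds)
    parts <- splitBySubject(ft, trainIds, testIds)
    imp <- featureImportanceFtest(parts$train, tr$importance_threshold)
    sel <- imp$feature[imp$selected]
    if (length(sel) < 2) sel <- imp$feature[!imp$screened]
    for (kind in tr$models) {
      fitted <- trainClassifier(kind, parts$train, features = sel,
                                cvK = tr$cv_k, seed = sy$seed)
      repKind <- evaluateClassifier(fitted, parts$test)
      reports[[kind]] <- repKind
      jsonlite::write_json(
        list(kind = kind, task = repKind@task,
             cv_accuracy = fitted@cvAccuracy,
             overall_accuracy = repKind@overallAccuracy,
             per_class_accuracy = as.list(repKind@perClassAccuracy),
             confusion = unclass(repKind@confusion),
             auc = repKind@auc, gini = repKind@gini,
             provenance = prov),
        file.path(outDir, sprintf("report_%s.json", kind)),
        auto_unbox = TRUE, digits = NA)
    }
  } else {
    .logStage("train", "disabled; stopping after stats")
  }
  invisible(list(features = ft, stats = rep, reports = reports))
}
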