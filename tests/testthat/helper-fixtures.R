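# Shared fixtures. Everything is generated in code; the one expensive object
# (the full default 17-subject cohort) is built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

# reduced cohort specs for fast tests: native 250 Hz synthesis, no lead-in
smallSpecs <- function(nSubjects = 6,
                       eps = c(resting = 4L, city_roadway = 6L,
                               expressway = 6L)) {
  sp <- defaultStateSpecs()
  for (st in names(sp)) {
    sp[[st]]@nSubjects <- as.integer(nSubjects)
    sp[[st]]@epochsPerSubject <- eps[[st]]
  }
  sp
}

noTrimConfig <- function(...) preprocessConfig(dropInitial = 0, ...)

# small cohort -> FeatureTable (native 250 Hz, no trim)
smallFeatureTable <- function(seed = 1, nSubjects = 6,
                              eps = c(resting = 4L, city_roadway = 6L,
                                      expressway = 6L)) {
  rec <- synthesizeCohort(smallSpecs(nSubjects, eps), seed = seed, fs = 250,
                          leadIn = 0)
  cfg <- noTrimConfig()
  ep <- segmentEpochs(preprocessRecording(rec, cfg), cfg)
  buildFeatureTable(epochSpectralFeatures(ep))
}

# the full study-scale cohort (17 subjects, 3/27/18 epochs, 1000 Hz native,
# 30 s lead-in trimmed by preprocessing); built once, shared by the epoch
# bookkeeping and parameter recovery tests
defaultCohort <- function(seed = 42) {
  key <- paste0("cohort", seed)
  if (is.null(.fixtureCache[[key]])) {
    cfg <- preprocessConfig()
    rec <- synthesizeCohort(defaultStateSpecs(), seed = seed, fs = 1000,
                            leadIn = 30)
    ep <- segmentEpochs(preprocessRecording(rec, cfg), cfg)
    sf <- epochSpectralFeatures(ep)
    .fixtureCache[[key]] <- list(ep = ep, spectral = sf,
                                 ft = buildFeatureTable(sf),
                                 targets = attr(rec, "targets"))
  }
  .fixtureCache[[key]]
}

# multichannel sinusoid recording with a single annotated segment
toneRecording <- function(freqHz, fs = 1000, durSec = 60, amp = 1,
                          state = "resting", subject = "S01") {
  t <- seq(0, durSec - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freqHz * t)
  dat <- cbind(Fp1 = x, Fp2 = x, O1 = x, O2 = x)
  rawRecording(dat, colnames(dat), rep("eeg", 4), fs,
               data.frame(onset = 0, duration = durSec, state = state,
                          subject = subject))
}

# independent single-periodogram band powers (oracle for the Welch path)
periodogramBandPowers <- function(x, fs, scheme = defaultBandScheme()) {
  n <- length(x)
  p <- abs(fft(x))^2 / (fs * n)
  nf <- floor(n / 2) + 1
  freqs <- (seq_len(nf) - 1) * fs / n
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  dens <- p[seq_len(nf)] * dbl
  df <- fs / n
  bm <- bandMatrix(scheme)
  vapply(rownames(bm), function(b)
    sum(dens[freqs >= bm[b, 1] & freqs < bm[b, 2]]) * df, numeric(1))
}

# exhaustive pair-counting AUC oracle (ties count 1/2)
pairCountAUC <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# sign-flip permutation p-value oracle for a paired comparison
permutationPairedP <- function(d, nPerm = 400, seed = 1) {
  set.seed(seed)
  obs <- abs(mean(d))
  hits <- 0
  for (i in seq_len(nPerm)) {
    flip <- sample(c(-1, 1), length(d), replace = TRUE)
    if (abs(mean(d * flip)) >= obs - 1e-12) hits <- hits + 1
  }
  hits / nPerm
}

# label-permutation importance oracle for the ANOVA-F selection
permutationImportance <- function(v, y, nPerm = 200, seed = 1) {
  fstat <- function(vv, yy)
    stats::oneway.test(vv ~ yy, var.equal = TRUE)$statistic
  obs <- fstat(v, y)
  set.seed(seed)
  hits <- 0
  for (i in seq_len(nPerm))
    if (fstat(v, sample(y)) >= obs - 1e-12) hits <- hits + 1
  1 - hits / nPerm
}
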