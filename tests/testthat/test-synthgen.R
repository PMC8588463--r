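# Synthetic EEG generator: calibration, determinism, power bookkeeping,
# artifact injection.

test_that("default state specs carry the published band means and sum to one", {
  specs <- defaultStateSpecs()
  pub <- publishedGlobalSummaries()
  for (st in names(specs)) {
    m <- specs[[st]]@bandRelMean
    expect_equal(sum(m), 1, tolerance = 1e-9)
    for (b in c("delta", "theta", "alpha", "beta", "gamma")) {
      printed <- pub$mean[pub$feature == b & pub$state == st]
      # printed means per state sum to ~1 already, so renormalization is tiny
      expect_lt(abs(m[[b]] - printed), 0.002)
    }
  }
  expect_lt(abs(specs$resting@bandRelMean[["delta"]] - 0.344), 0.001)
  expect_lt(abs(specs$city_roadway@bandRelMean[["gamma"]] - 0.047), 0.001)
  # raw printed means sum to 1 +/- 0.01 per state
  for (st in names(specs)) {
    raw <- sum(pub$mean[pub$state == st &
                          pub$feature %in% c("delta", "theta", "alpha",
                                             "beta", "gamma")])
    expect_lt(abs(raw - 1), 0.01)
  }
})

test_that("a single-band spec yields a near-pure alpha epoch", {
  eps <- 1e-6
  spec <- stateSpec("resting",
                    bandRelMean = c(delta = eps, theta = eps,
                                    alpha = 1 - 4 * eps, beta = eps,
                                    gamma = eps),
                    bandRelSD = setNames(rep(0, 5),
                                         c("delta", "theta", "alpha", "beta",
                                           "gamma")),
                    nSubjects = 1, epochsPerSubject = 1)
  rec <- synthesizeRecording(spec, seed = 3, fs = 250, leadIn = 0)
  bp <- bandPowers(welchPSD(t(recordingData(rec)), 250))
  alpha <- bp$rel_power[bp$band == "alpha"]
  expect_true(all(alpha >= 0.95))
  expect_true(all(bp$rel_power[bp$band != "alpha"] <= 0.05))
})

test_that("synthesis is a pure function of (spec, seed)", {
  spec <- smallSpecs(2, c(resting = 2L, city_roadway = 2L,
                          expressway = 2L))$resting
  a <- synthesizeRecording(spec, seed = 9, fs = 250, leadIn = 0)
  b <- synthesizeRecording(spec, seed = 9, fs = 250, leadIn = 0)
  c <- synthesizeRecording(spec, seed = 10, fs = 250, leadIn = 0)
  expect_identical(recordingData(a), recordingData(b))
  expect_identical(attr(a, "targets"), attr(b, "targets"))
  expect_false(identical(recordingData(a), recordingData(c)))
})

test_that("the resting cohort recovers its spec delta mean (Monte Carlo)", {
  spec <- defaultStateSpecs()$resting   # 17 subjects x 3 epochs
  rec <- synthesizeRecording(spec, seed = 42, fs = 250, leadIn = 0)
  cfg <- noTrimConfig()
  ep <- segmentEpochs(rec, cfg)
  sf <- epochSpectralFeatures(ep)
  expect_lt(abs(mean(sf$global_delta_relpow) - 0.344), 0.05)
})

test_that("clean epoch variance matches the spec total power within 5%", {
  spec <- smallSpecs(3, c(resting = 3L, city_roadway = 3L,
                          expressway = 3L))$city_roadway
  rec <- synthesizeRecording(spec, seed = 4, fs = 250, leadIn = 0)
  dat <- recordingData(rec)
  nEp <- nrow(dat) / 2500
  v <- vapply(seq_len(nEp), function(i)
    mean(apply(dat[(i - 1) * 2500 + seq_len(2500), ], 2, var)), numeric(1))
  expect_true(all(abs(v - spec@totalPower) / spec@totalPower < 0.05))
})

test_that("realized Welch relative powers track the drawn targets", {
  spec <- defaultStateSpecs()$city_roadway
  spec@nSubjects <- 5L
  spec@epochsPerSubject <- 5L
  rec <- synthesizeRecording(spec, seed = 7, fs = 250, leadIn = 0)
  tg <- attr(rec, "targets")
  dat <- recordingData(rec)
  err <- matrix(0, nrow(tg), 5)
  for (i in seq_len(nrow(tg))) {
    idx <- (i - 1) * 2500 + seq_len(2500)
    bp <- bandPowers(welchPSD(t(dat[idx, ]), 250))
    rel <- vapply(colnames(tg), function(b)
      mean(bp$rel_power[bp$band == b]), numeric(1))
    err[i, ] <- rel - tg[i, ]
  }
  # per-epoch agreement is bounded by Welch estimator variance: ~95% of
  # epochs within +/-0.03, all within 0.1
  expect_gte(mean(abs(err) <= 0.03), 0.90)
  expect_lt(max(abs(err)), 0.1)
  expect_lt(max(abs(colMeans(err))), 0.03)   # no systematic bias
})

test_that("invalid specs are rejected", {
  m <- c(delta = 0.3, theta = 0.2, alpha = 0.2, beta = 0.2, gamma = 0.1)
  s <- setNames(rep(0.05, 5), names(m))
  expect_error(stateSpec("resting", m, -s), "SD")
  bad <- m
  bad["gamma"] <- 0
  expect_error(stateSpec("resting", bad, s), "positive")
})

test_that("artifact injection with all rates zero is a no-op", {
  rec <- toneRecording(10, fs = 250, durSec = 20)
  out <- injectArtifacts(rec, blinkRate = 0, emgBurstRate = 0, lineAmp = 0,
                         seed = 1)
  expect_identical(recordingData(out$recording), recordingData(rec))
  expect_identical(out$clean, rec)
  expect_equal(nrow(out$events), 0)
})

test_that("a power-line artifact creates a 60 Hz peak absent from the input", {
  spec <- smallSpecs(1, c(resting = 2L, city_roadway = 2L,
                          expressway = 2L))$resting
  rec <- synthesizeRecording(spec, seed = 5, fs = 250, leadIn = 0)
  out <- injectArtifacts(rec, blinkRate = 0, emgBurstRate = 0, lineAmp = 10,
                         seed = 2)
  lineBand <- function(r) {
    psd <- welchPSD(t(recordingData(r)[seq_len(2500), 1, drop = FALSE]), 250)
    sum(psd@power[1, psd@freqs >= 59 & psd@freqs <= 61])
  }
  expect_gt(lineBand(out$recording) / lineBand(rec), 50)
})

test_that("blink events in the log match threshold crossings on the EOG", {
  rec <- toneRecording(10, fs = 250, durSec = 60, amp = 1)
  out <- injectArtifacts(rec, blinkRate = 0.25, emgBurstRate = 0,
                         lineAmp = 0, seed = 11)
  nBlinks <- sum(out$events$kind == "blink")
  expect_gt(nBlinks, 0)    # Poisson(15), zero is essentially impossible
  eog <- recordingData(out$recording)[, "EOG"]
  # count rising threshold crossings at half the blink reference amplitude
  above <- eog > 100
  crossings <- sum(diff(above) == 1) + as.integer(above[1])
  expect_equal(crossings, nBlinks)
  expect_true(all(c("EOG", "EMG") %in% channelNames(out$recording)))
  expect_identical(channelRoles(out$recording)[["EOG"]], "eog")
})

test_that("injection rejects negative rates", {
  rec <- toneRecording(10, fs = 250, durSec = 10)
  expect_error(injectArtifacts(rec, blinkRate = -1, emgBurstRate = 0,
                               lineAmp = 0, seed = 1), ">= 0")
})
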