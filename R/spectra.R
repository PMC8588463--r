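# Welch power spectral density and the frequency-domain feature set:
# absolute/relative/mean band powers, median and power-weighted mean
# frequency, 90% spectral edge and peak frequency, with frontal/occipital/
# global channel aggregation.

#' Welch power spectral density
#'
#' Averages Hamming-windowed, 50%-overlapping segment periodograms into a
#' one-sided density estimate. With the default 2-s segments the grid
#' resolution is 0.5 Hz, giving at least seven bins inside the delta band.
#' The estimate is Parseval-consistent: the density integrated over
#' (0, fs/2) matches the signal variance (plus squared mean at DC).
#'
#' @param x numeric vector (one channel) or channels-in-rows matrix; length
#'   must be a whole number of segments (an epoch).
#' @param fs sampling rate (Hz).
#' @param segmentSeconds Welch segment length (s).
#' @param overlap fractional segment overlap in `[0, 1)`.
#' @param channels channel names (defaults to rownames or ch1..chK).
#' @return a [PSDEstimate-class].
#' @examples
#' fs <- 250
#' t <- seq(0, 10 - 1 / fs, by = 1 / fs)
#' psd <- welchPSD(sin(2 * pi * 10 * t), fs)
#' psd@freqs[which.max(psd@power[1, ])]  # 10 Hz
#' @export
welchPSD <- function(x, fs, segmentSeconds = 2, overlap = 0.5,
                     channels = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (anyNA(x)) stop("epoch contains NA values")
  n <- ncol(x)
  L <- round(segmentSeconds * fs)
  if (n < L) stop("epoch shorter than one Welch segment")
  step <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, n - L + 1, by = step)
  w <- signal::hamming(L)
  scale <- fs * sum(w^2)
  nf <- floor(L / 2) + 1
  freqs <- (seq_len(nf) - 1) * fs / L
  if (is.null(channels))
    channels <- rownames(x) %||% paste0("ch", seq_len(nrow(x)))
  pw <- matrix(0, nrow(x), nf, dimnames = list(channels, NULL))
  for (ch in seq_len(nrow(x))) {
    acc <- numeric(nf)
    for (s in starts) {
      seg <- x[ch, s:(s + L - 1)] * w
      sp <- abs(fft(seg))^2 / scale
      acc <- acc + sp[seq_len(nf)]
    }
    acc <- acc / length(starts)
    # one-sided: double everything except DC (and Nyquist when L is even)
    dbl <- rep(2, nf)
    dbl[1] <- 1
    if (L %% 2 == 0) dbl[nf] <- 1
    pw[ch, ] <- acc * dbl
  }
  new("PSDEstimate", freqs = freqs, power = pw, channels = channels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.bandBins <- function(freqs, low, high) which(freqs >= low & freqs < high)

#' Band powers from a PSD estimate
#'
#' Absolute band power is the density summed times the bin width over the
#' half-open band `[low, high)`; relative power divides by the total power
#' over the scheme's full range; mean power divides by the band width.
#'
#' @param psd a [PSDEstimate-class].
#' @param scheme a [BandScheme-class].
#' @return data.frame with columns `channel`, `band`, `abs_power`,
#'   `rel_power`, `mean_power`, plus one `total_power` value per channel in
#'   the attribute `"total_power"`. Relative powers are `NA` (flagged) for a
#'   zero-total-power channel.
#' @export
bandPowers <- function(psd, scheme = defaultBandScheme()) {
  stopifnot(is(psd, "PSDEstimate"))
  df <- psd@freqs[2] - psd@freqs[1]
  bm <- bandMatrix(scheme)
  tot <- .bandBins(psd@freqs, scheme@totalRange[1], scheme@totalRange[2])
  totalPower <- rowSums(psd@power[, tot, drop = FALSE]) * df
  out <- do.call(rbind, lapply(rownames(bm), function(b) {
    bins <- .bandBins(psd@freqs, bm[b, 1], bm[b, 2])
    absp <- rowSums(psd@power[, bins, drop = FALSE]) * df
    data.frame(channel = psd@channels, band = b, abs_power = absp,
               rel_power = ifelse(totalPower > 0, absp / totalPower, NA),
               mean_power = absp / (bm[b, 2] - bm[b, 1]))
  }))
  rownames(out) <- NULL
  attr(out, "total_power") <- setNames(totalPower, psd@channels)
  out
}

# cumulative-power quantile crossing, linearly interpolated at bin right
# edges; bin at grid frequency f carries the power of [f, f + df)
.quantileFreq <- function(freqs, dens, q) {
  df <- freqs[2] - freqs[1]
  cum <- c(0, cumsum(dens * df))
  edges <- c(freqs, freqs[length(freqs)] + df)
  target <- q * cum[length(cum)]
  i <- which(cum >= target)[1]
  if (i == 1) return(edges[1])
  edges[i - 1] + df * (target - cum[i - 1]) / (cum[i] - cum[i - 1])
}

#' Spectral summary frequencies per band
#'
#' Per channel and band: the median frequency (50% cumulative-power
#' crossing), the power-weighted mean frequency, the 90% spectral edge and
#' the peak (argmax-density) frequency. Quantile crossings are interpolated
#' linearly between bins. A zero-power band yields `NA` summaries.
#'
#' @inheritParams bandPowers
#' @return data.frame with columns `channel`, `band`, `median_freq`,
#'   `mean_freq`, `edge_freq`, `peak_freq`.
#' @export
spectralSummaries <- function(psd, scheme = defaultBandScheme()) {
  stopifnot(is(psd, "PSDEstimate"))
  bm <- bandMatrix(scheme)
  out <- do.call(rbind, lapply(rownames(bm), function(b) {
    bins <- .bandBins(psd@freqs, bm[b, 1], bm[b, 2])
    f <- psd@freqs[bins]
    res <- t(vapply(seq_along(psd@channels), function(ch) {
      d <- psd@power[ch, bins]
      if (sum(d) <= 0) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
      c(.quantileFreq(f, d, 0.5),
        sum(f * d) / sum(d),
        .quantileFreq(f, d, 0.9),
        f[which.max(d)])
    }, numeric(4)))
    data.frame(channel = psd@channels, band = b, median_freq = res[, 1],
               mean_freq = res[, 2], edge_freq = res[, 3],
               peak_freq = res[, 4])
  }))
  rownames(out) <- NULL
  out
}

.LOBES <- list(frontal = c("Fp1", "Fp2"), occipital = c("O1", "O2"),
               global = c("Fp1", "Fp2", "O1", "O2"))

#' Aggregate per-channel features over lobes
#'
#' Adds `frontal` (mean of Fp1, Fp2), `occipital` (mean of O1, O2) and
#' `global` (mean of all four channels) rows to a per-channel feature
#' data.frame. Aggregates are unweighted means of the per-channel feature
#' values; an aggregate is `NA` if any constituent channel is missing.
#'
#' @param features data.frame with a `channel` column, optional grouping
#'   columns (e.g. `band`), and numeric feature columns.
#' @return the input with aggregate rows appended.
#' @export
aggregateChannels <- function(features) {
  stopifnot("channel" %in% names(features))
  groupCols <- intersect(c("band", "epoch"), names(features))
  valCols <- setdiff(names(features), c("channel", groupCols))
  key <- if (length(groupCols))
    interaction(features[groupCols], drop = TRUE) else factor(rep(1, nrow(features)))
  agg <- do.call(rbind, lapply(names(.LOBES), function(lb) {
    chans <- .LOBES[[lb]]
    do.call(rbind, lapply(levels(key), function(k) {
      sub <- features[key == k & features$channel %in% chans, , drop = FALSE]
      row <- sub[1, , drop = FALSE]
      row$channel <- lb
      for (v in valCols)
        row[[v]] <- if (nrow(sub) == length(chans)) mean(sub[[v]]) else NA
      row
    }))
  }))
  out <- rbind(features, agg)
  rownames(out) <- NULL
  out
}

#' Per-epoch spectral feature extraction
#'
#' Runs [welchPSD()] on every epoch and assembles the per-channel and
#' aggregated base features: band relative powers, band summary frequencies,
#' per-channel total power, and per-channel delta-alpha/delta-theta ratios.
#'
#' @param ep an [EpochedRecording-class].
#' @param scheme a [BandScheme-class].
#' @param segmentSeconds,overlap Welch parameters.
#' @return data.frame, one row per epoch: `epoch`, `subject`, `state`, then
#'   the named base feature columns (see [featureColumns()]).
#' @export
epochSpectralFeatures <- function(ep, scheme = defaultBandScheme(),
                                  segmentSeconds = 2, overlap = 0.5) {
  stopifnot(is(ep, "EpochedRecording"))
  n <- nEpochs(ep)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    psd <- welchPSD(ep@epochs[i, , ], ep@fs, segmentSeconds, overlap,
                    channels = ep@channels)
    bp <- bandPowers(psd, scheme)
    sm <- spectralSummaries(psd, scheme)
    totals <- attr(bp, "total_power")
    vals <- list()
    # per-channel band features
    for (ch in psd@channels) {
      for (b in bandNames(scheme)) {
        r <- bp[bp$channel == ch & bp$band == b, ]
        s <- sm[sm$channel == ch & sm$band == b, ]
        vals[[paste(ch, b, "relpow", sep = "_")]] <- r$rel_power
        vals[[paste(ch, b, "medfreq", sep = "_")]] <- s$median_freq
        vals[[paste(ch, b, "meanfreq", sep = "_")]] <- s$mean_freq
        vals[[paste(ch, b, "edgefreq", sep = "_")]] <- s$edge_freq
        vals[[paste(ch, b, "peakfreq", sep = "_")]] <- s$peak_freq
      }
      rel <- setNames(bp$rel_power[bp$channel == ch], bp$band[bp$channel == ch])
      dd <- deltaRatios(rel[["delta"]], rel[["theta"]], rel[["alpha"]])
      vals[[paste0(ch, "_dar")]] <- dd[["dar"]]
      vals[[paste0(ch, "_dtr")]] <- dd[["dtr"]]
      vals[[paste0(ch, "_total_pow")]] <- totals[[ch]]
    }
    # lobe/global aggregates of relative power
    relDf <- bp[, c("channel", "band", "rel_power")]
    aggd <- aggregateChannels(relDf)
    for (lb in names(.LOBES))
      for (b in bandNames(scheme))
        vals[[paste(lb, b, "relpow", sep = "_")]] <-
          aggd$rel_power[aggd$channel == lb & aggd$band == b]
    rows[[i]] <- as.data.frame(vals)
  }
  out <- do.call(rbind, rows)
  data.frame(epoch = seq_len(n), subject = ep@subject, state = ep@state,
             out, check.names = FALSE)
}
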