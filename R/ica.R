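# Fixed-point ICA (symmetric decorrelation, tanh contrast) for
# reference-guided artifact removal. With four EEG channels the decomposition
# is rank-limited to four components; EOG/EMG reference channels never enter
# the unmixing, they only identify which components to discard.

.fastICA <- function(X, nComp = ncol(X), maxIter = 500, tol = 1e-6) {
  # X: samples x channels
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  cv <- crossprod(Xc) / (n - 1)
  e <- eigen(cv, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-12
  K <- e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep))
  nComp <- min(nComp, sum(keep))
  Z <- Xc %*% K                               # whitened, samples x comps
  # fixed, RNG-free initialization keeps the decomposition deterministic
  W <- matrix(sin(seq_len(nComp * nComp)), nComp)
  sym <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym(W)
  it <- 0
  repeat {
    it <- it + 1
    WX <- Z %*% t(W)                          # samples x comps
    G <- tanh(WX)
    gd <- colMeans(1 - G^2)
    W1 <- t(G) %*% Z / n - diag(gd, nComp) %*% W
    W1 <- sym(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
    if (it >= maxIter) {
      # near-Gaussian sources have no unique rotation; any orthonormal W
      # still reconstructs the signal exactly, so continue with a warning
      warning(sprintf(
        "ICA did not converge after %d iterations (delta %.2e); using the
current estimate", it, delta))
      break
    }
  }
  S <- Z %*% t(W)                             # sources, samples x comps
  list(S = S, W = W, K = K, mean = mu, iterations = it)
}

# reconstruct samples x channels from (possibly zeroed) sources
.icaReconstruct <- function(dec, S) {
  # Z = Xc K, S = Z W'; W orthonormal => Z = S W; Xc = Z K^{-1}
  Z <- S %*% dec$W
  Kinv <- MASS::ginv(dec$K)
  sweep(Z %*% Kinv, 2, dec$mean, `+`)
}

#' Remove ocular and muscular artifacts with reference-guided ICA
#'
#' Decomposes the EEG channels into independent components (fixed-point ICA,
#' tanh contrast, symmetric decorrelation), zeroes every component whose
#' absolute Pearson correlation with the EOG or EMG reference exceeds
#' `cfg@icaThreshold`, and reconstructs the signal from the remaining
#' components. Channel count, order and length are preserved. If no component
#' exceeds the threshold the input is passed through with a warning.
#'
#' @param rec a [RawRecording-class] whose EEG channels are to be cleaned.
#' @param eog,emg numeric reference vectors time-aligned with `rec` (pass
#'   `NULL` to skip one); by default taken from channels with role
#'   `"eog"`/`"emg"` inside `rec`.
#' @param cfg a [PreprocessConfig-class] (threshold; `icaEnabled = FALSE`
#'   passes through untouched).
#' @return a new [RawRecording-class]; attribute `"ica_removed"` lists the
#'   indices of zeroed components.
#' @export
removeArtifactsICA <- function(rec, eog = NULL, emg = NULL,
                               cfg = preprocessConfig()) {
  stopifnot(is(rec, "RawRecording"))
  if (!cfg@icaEnabled) return(rec)
  eegIdx <- which(rec@roles == "eeg")
  if (length(eegIdx) < 4) stop("ICA cleaning requires >= 4 EEG channels")
  if (is.null(eog) && any(rec@roles == "eog"))
    eog <- rec@data[, which(rec@roles == "eog")[1]]
  if (is.null(emg) && any(rec@roles == "emg"))
    emg <- rec@data[, which(rec@roles == "emg")[1]]
  refs <- Filter(Negate(is.null), list(eog = eog, emg = emg))
  if (!length(refs))
    stop("at least one EOG or EMG reference is required")
  for (r in refs) if (length(r) != nrow(rec@data))
    stop("reference channels must be time-aligned with the recording")

  X <- rec@data[, eegIdx, drop = FALSE]
  dec <- .fastICA(X)
  S <- dec$S
  bad <- logical(ncol(S))
  for (r in refs)
    if (sd(r) > 0)
      bad <- bad | apply(S, 2, function(s)
        abs(stats::cor(s, r)) > cfg@icaThreshold)
  if (!any(bad)) {
    warning("no independent component exceeded the reference-correlation ",
            "threshold; returning input unchanged")
    out <- rec
    attr(out, "ica_removed") <- integer()
    return(out)
  }
  S[, bad] <- 0
  Xclean <- .icaReconstruct(dec, S)
  dat <- rec@data
  dat[, eegIdx] <- Xclean
  out <- rawRecording(dat, rec@channels, rec@roles, rec@fs, rec@annotations)
  attr(out, "targets") <- attr(rec, "targets")
  attr(out, "ica_removed") <- which(bad)
  out
}
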