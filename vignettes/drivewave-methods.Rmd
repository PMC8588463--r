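---
title: "Methods: EEG spectral biomarkers of driving-induced mental workload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG spectral biomarkers of driving-induced mental workload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Driving imposes a mental workload that is visible in the scalp EEG: slow
(delta, theta) activity rises and fast (beta, gamma) activity falls relative
to a resting baseline, and composite ratios such as the delta--alpha ratio
(DAR) and delta--theta ratio (DTR) separate resting from driving states.
`drivewave` implements the full desk-scale analysis for a low-density montage
(prefrontal Fp1/Fp2, occipital O1/O2): synthetic cohort generation,
preprocessing, Welch spectral features, composite biomarkers, descriptive and
paired statistics, and class-imbalance-aware classification of the
neurological state (resting, city-roadway driving, expressway driving).

The measurement model is the band relative power
$$ e_j = \frac{\sum_{f \in [f_{j,\mathrm{lo}},\, f_{j,\mathrm{hi}})} P(f)\,\Delta f}
              {\sum_{f \in [0.5,\, 44)} P(f)\,\Delta f}, $$
with $P(f)$ the one-sided Welch power spectral density of a 10-s epoch and
bands delta $[0.5,4)$, theta $[4,8)$, alpha $[8,13)$, beta $[13,30)$, gamma
$[30,44)$ Hz. Derived biomarkers are $\mathrm{DAR} = e_\delta/e_\alpha$,
$\mathrm{DTR} = e_\delta/e_\theta$, the frontal asymmetry
$A = (e_R - e_L)/(e_R + e_L)$ for the Fp2/Fp1 pair, and the baseline-relative
change $\Delta e = (e - \bar{e}_r)/\bar{e}_r$ where $\bar{e}_r$ is the
subject's mean over resting epochs.

## The synthetic cohort generator

No public recordings accompany the study conditions, so the generator is a
first-class, calibrated component, not a test fixture. Its defaults *are* the
study conditions: 17 subjects; 10-s epochs; per-state global band
relative-power means and SDs set to the published state table (resting delta
0.344 +/- 0.284, city-roadway delta 0.477 +/- 0.088, and so on); 3 resting,
27 city-roadway and 18 expressway epochs per subject (51/459/306 in total)
with a 30-s lead-in per segment that preprocessing trims; native 1000 Hz
sampling to exercise the downsampling stage; total epoch power 100 uV^2
(a typical broadband scalp EEG variance -- only relative powers matter
downstream).

The recorded durations stated for the tasks (1, 5 and 4 minutes) are
internally inconsistent with the published epoch counts for the expressway
state: 4 minutes minus the 30-s trim yields 21 epochs, not the published 18
per subject. The generator follows the epoch counts (expressway segments of
210 s including lead-in), since every downstream size in the study derives
from the 51/459/306 bookkeeping.

**Per-epoch band targets.** Each epoch's five band fractions are drawn
hierarchically:

1. delta from a logit-normal whose $(\mu, \sigma)$ are moment-matched
   (Gauss--Hermite quadrature plus Nelder--Mead) to the state's printed
   mean/SD;
2. the remaining four bands as logit-normal shares, moment-matched to their
   printed moments rescaled by $1/(1 - \bar{e}_\delta)$, renormalized and
   multiplied by $1 - \delta$.

Anchoring on delta is deliberate. If all five bands are drawn independently
and renormalized, the normalization cancels inside DAR and DTR, making
$E[\mathrm{DAR}] = E[e_\delta]\,E[1/e_\alpha]$ -- about 3.3 at the resting
calibration, *below* the driving states' 3.7--4.1, the opposite of the
published direction (resting DAR 11.3 vs city 4.3). With delta anchored, a
large delta draw necessarily depresses alpha and theta, producing exactly the
heavy right tail that makes the resting mean ratio large (the resting delta SD
of 0.284 is what feeds the tail). Band means are preserved (within 0.002 of
the calibration at n = 20,000) and the published direction emerges rather
than being imposed. A per-subject random effect shifts each band's
logit-scale location with SD equal to half the between-epoch SD; the paper
reports no variance decomposition, so this split is a modelling choice.

**Waveforms.** Each 10-s block of each channel is the sum of five
band-limited Gaussian noise components, each scaled to realize its target
band variance exactly. Components are synthesized by frequency-domain
shaping: white Gaussian noise is Fourier transformed, multiplied by a
cosine-tapered in-band mask (taper width one quarter of the bandwidth, capped
at 1 Hz), inverted, and variance-normalized. A time-domain Butterworth
band-pass was rejected for this role: a 4th-order band-pass at 0.5--4 Hz out
of 1000 Hz is numerically unstable in double precision (the filtered variance
overflows), while the spectral route is exact and stable at every band.

**What the generator does and does not emulate.** It reproduces per-state
band composition, between-epoch and between-subject variability, epoch
bookkeeping, and (optionally) eye-blink transients with an EOG reference,
high-frequency EMG bursts with an EMG reference, and a 60 Hz line component.
It does not attempt a 1/f spectral background, within-epoch nonstationarity,
epoch-to-epoch waveform continuity (blocks are stitched independently;
epoch boundaries coincide with block boundaries), volume-conduction
correlation between channels, or real artifact morphology beyond smooth
transients and band-limited bursts. Passing recovery tests on this generator
therefore validates the *pipeline arithmetic* under known ground truth, not
the biology of real recordings.

**Realized accuracy.** Because band component variances are scaled exactly,
epoch total power matches the specification to within sampling arithmetic.
Welch-measured per-epoch relative powers track their targets within +/-0.03
for at least 90% of epochs; the residual tail (up to ~0.07) is Welch
estimator variance -- nine 2-s Hamming segments per epoch -- not synthesis
error. Cohort means recover the calibration within +/-0.05 per band and
state, the tolerance used by the acceptance checks.

## Preprocessing

The cleaning chain applies, in order: a 2nd-order Butterworth band-stop
(59--61 Hz, Q ~ 30 equivalent) at the line frequency; a 6th-order Butterworth
anti-aliasing low-pass at 0.8x the target Nyquist followed by decimation from
1000 Hz to 250 Hz; optional reference-guided ICA; and a 4th-order Butterworth
band-pass at 0.5--44 Hz. Every IIR filter runs forward-backward
(`signal::filtfilt`), because phase distortion would bias the left/right
asymmetry index. Filter families and orders are standard EEG practice; the
study names only the corner frequencies.

Segmentation drops the first 30 s of every annotated task segment
(instrument settling), then cuts consecutive non-overlapping 10-s epochs,
discarding trailing partials: `floor((duration - 30)/10)` epochs per segment.

One consequence of band-passing at exactly the gamma band's upper edge: the
zero-phase 4th-order response has mean squared-magnitude ~0.68 across
30--44 Hz, so recovered gamma relative power sits ~0.01--0.035 below its
synthesis target (largest for the gamma-rich resting state). This is a
property of the stated filter design, shared by any faithful implementation,
and stays inside the +/-0.05 recovery tolerance.

**ICA.** Artifact removal uses a fixed-point ICA (tanh contrast, symmetric
decorrelation, deterministic RNG-free initialization) on the four EEG
channels; components whose absolute Pearson correlation with the EOG or EMG
reference exceeds 0.7 (configurable) are zeroed before reconstruction. The
correlation rule makes the rejection criterion explicit -- the study says
only that ICA "utilized" the reference recordings. Two edge cases are
handled deliberately: with near-Gaussian sources (clean synthetic EEG) the
rotation is not identifiable and the iteration may not converge -- since any
orthonormal rotation reconstructs the data exactly, the current estimate is
used with a warning; and if no component crosses the threshold the input
passes through unchanged, with a warning rather than an error.

## Spectral features

The Welch estimate averages Hamming-windowed 2-s segments with 50% overlap
(nine per epoch), giving 0.5 Hz bins -- at least seven inside the narrowest
band -- as the resolution/variance compromise behind the study's "10%
hamming" shorthand. Band bins follow the half-open convention `[low, high)`,
so 4.0 Hz is theta, never delta, and the bands tile 0.5--44 Hz without double
counting. Per band and channel the package reports: relative power (the
denominator is the same epoch's 0.5--44 Hz total), median frequency (50%
cumulative-power crossing, linearly interpolated with each bin's mass spread
over `[f, f + df)`), mean frequency (power-weighted mean -- the literal
"frequency at which the average power is reached" is multi-valued and was
read as the spectral centroid), 90% spectral edge, and peak frequency.
Frontal, occipital and global aggregates are unweighted means of per-channel
feature values (averaging per-channel relative powers, not re-ratioing
pooled powers), matching the per-channel feature inventory.

## Biomarkers and the 149-column table

Baselines are per subject (the mean over that subject's resting epochs), so
baseline-relative features remain computable for a new subject at inference
time. DAR and DTR are computed per epoch and channel and *then* averaged for
reporting. The published tables force this mean-of-ratios reading: the
printed resting global DAR (11.330) is far from the ratio of the printed
mean band powers (0.344/0.124 = 2.8), which is only possible if skewed
per-epoch ratios were averaged. Asymmetry is computed for the frontal pair
only (Fp2 right, Fp1 left), as in the study; its offsets in the generator
default to zero because no numeric asymmetry values are published.

The epoch-by-feature table holds exactly 149 columns:
100 per-channel band features (4 channels x 5 bands x {relative power,
median/mean/edge/peak frequency}), 5 global and 10 lobe band relative
powers, 10 lobe baseline-changes, 8 per-channel DAR/DTR, 8 their
baseline-changes, 4 per-channel total powers (uV^2) and 4 their
baseline-changes. The published inventory labels the per-band quantity
"mean power"; every printed statistic operates on relative powers, so the
relative power is the tabulated power feature and column names say so
(`Fp1_delta_relpow`, `d_frontal_beta_relpow`, `O2_dar`, ...). Change
columns for DAR/DTR divide by the subject's resting DAR/DTR (the
baseline-relative rule applied to the feature itself, not recomputed from
changed band powers).

## Statistics

Per-state descriptives use the t-based 95% CI,
$\bar{x} \pm t_{0.975,\,n-1}\, s/\sqrt{n}$. Paired comparisons aggregate
epochs to one value per subject per state before a two-sided paired t-test:
epoch counts are unbalanced across states (3 vs 27 per subject), and the
pairing unit must be the subject. No normality screening and no
multiple-testing correction are applied, mirroring the study's analysis; the
report carries the number of tests so a reader can apply their own
correction. Band-vs-band relations are ordinary least squares; the slope and
Pearson r are reported as separate fields and never conflated (the study
prints "correlation coefficients" with magnitudes above 1, which can only be
slopes). $R^2 = r^2$ holds to numerical precision for these simple
regressions and is asserted in tests.

## Feature selection and classification

Selection screens out constant/missing features, then scores each remaining
feature with a one-way ANOVA F-test across the three states; importance is
$1 - p$ and features with importance above 0.95 are kept. Selection runs on
the training partition only -- the study does not say whether its 112/149
features were selected before or after the train/test split; selecting on
training data is the leakage-safe reading. The split itself is by subject
(12 train / 5 test), never by epoch.

Class imbalance (51 resting vs 765 driving epochs) is handled with
inverse-frequency weights $w_c = N/(K n_c)$: LDA receives them as adjusted
priors, the RBF-SVM as class weights, the gain-ratio tree as case weights,
and KNN and the univariate tree as vote/leaf weights. Distance- and
kernel-based families (KNN, LDA, SVM) see z-scored features (parameters
estimated on the training partition); trees see raw values.

Model families: KNN with k = 3 and nearest-neighbour tie-breaking; linear
discriminant analysis; SVM with Gaussian kernel
$K(x_1, x_2) = \exp(-\gamma \lVert x_1 - x_2\rVert^2)$, $\gamma = 1/p$ on
standardized features; a gain-style information-split decision tree with
cost-complexity pruning standing in for the proprietary C5.0; and a
univariate binary-split tree whose split variable is chosen by per-feature
ANOVA tests before any split point is searched -- the unbiased-selection
trait of QUEST. The last two are documented approximations: bit-level
reproduction of legacy commercial implementations is neither possible nor
claimed. Cross-validation is stratified 10-fold with seed-controlled
shuffling; fold counts shrink (with a warning) when a class has fewer rows
than folds.

Reports contain the actual-by-predicted confusion matrix, per-class
(diagonal over row sum) and overall (trace over total) accuracies, and for
binary tasks the ROC from model scores, the trapezoid AUC and the Gini
coefficient $2\,\mathrm{AUC} - 1$. The study's prose defines Gini as
"two times (AUC - 1)", which contradicts every printed table (AUC 0.667 with
Gini 0.334); the tables govern. Predictor importances are estimated by
permutation (accuracy drop under single-feature shuffling) uniformly across
model families.

## Numerical choices and test problem sizes

* Logit-normal moment matching: 48-node Gauss--Hermite quadrature,
  Nelder--Mead on $(\mu, \log\sigma)$, relative tolerance 1e-14; an SD of 0
  degenerates to a point mass.
* Quantile crossings in spectral summaries are linearly interpolated; a
  zero-power band yields missing summaries; a zero-total-power epoch yields
  missing relative powers and is excluded downstream.
* Zero baselines, zero ratio denominators and both-zero asymmetry inputs
  produce missing values (with warnings), never infinities.
* KNN vote ties break to the nearest neighbour's class; tree leaves predict
  the weight-adjusted majority.
* The test suite validates parameter recovery and epoch bookkeeping on one
  full-scale cohort (17 subjects, 51/459/306 epochs, native 1000 Hz, built
  once and shared across tests), and direction properties (resting vs
  driving separability and DAR/DTR ordering) on twenty seeded scaled-down
  cohorts (10 subjects, 6 epochs per state, native 250 Hz) -- sizes chosen so
  the full suite stays desk-scale while the sampling distributions of the
  checked statistics remain tight.
* Determinism: every stochastic step (synthesis, fold shuffling,
  permutation importance) is a pure function of an integer seed; the ICA
  initialization is fixed and RNG-free.

## Known limitations

* Synthetic validation only: the study's recordings are unavailable, so
  published t/p values and classifier accuracies on real data are not
  reproduction targets -- only their self-consistent worked arithmetic is.
* The generator's independence assumptions (bands independent given delta,
  channels independent, epochs independent) are simplifications; real EEG
  has cross-channel and temporal structure that would reduce effective
  sample sizes.
* EDF support is a minimal plain-EDF reader/writer (16-bit, one sampling
  rate, annotations in a plain-text sidecar), sufficient for round-tripping
  the generator's output, not a general EDF+ implementation.
* The C5.0- and QUEST-style trees reproduce each algorithm's defining trait,
  not the exact software behaviour of the originals.
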