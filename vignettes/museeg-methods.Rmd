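---
title: "Decoding music-evoked emotions from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding music-evoked emotions from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(museeg)
```

## The problem

Music reliably evokes emotions — calm, joy, sadness, anger — and these
states leave measurable traces in the scalp EEG. `museeg` implements a
complete analysis chain for asking *which* EEG features carry that
emotional information: per-electrode extraction of 18 linear band features
and 9 nonlinear dynamics features, correlation-based feature selection
(CFS) over the resulting 27-dimensional description, and multi-classifier
verification of the selected subsets. Because the recordings behind the
original experimental design are not publicly deposited, the package ships
a synthetic EEG generator whose class structure is controllable, so every
stage is testable end to end and all reported numbers are reproducible
from code.

The reference design the defaults mirror: 15 datasets (volunteer
sessions), 20 trials per emotion per dataset (80 trials), 12 electrodes
(FP1, FP2, F3, F4, F7, F8, Fz, C3, C4, T3, T4, Pz), 256 Hz sampling, and a
15 s analysis epoch taken from the middle of each 45 s music trial.

## The synthetic generator

Each channel-epoch is synthesized as

\[
x(t) \;=\; \sum_{b \in \{\theta,\alpha,\beta\}} A_b \sin(2\pi f_b t + \phi)
\;+\; c \cdot \sigma_{\mathrm{osc}} \, z(t) \;+\; \varepsilon(t),
\]

where the band amplitudes \(A_b\) (microvolts) and centre frequencies
\(f_b\) depend on the emotion, \(z(t)\) is a standardized logistic-map
sequence (\(z_{t+1} = 4 z_t (1-z_t)\)) weighted by the emotion's chaos
fraction \(c\), and \(\varepsilon\) is white noise. The logistic map was
chosen deliberately: its largest Lyapunov exponent is known analytically
(\(\ln 2\)), giving a free oracle for the Lyapunov estimator, and its
positive correlation entropy exercises K2. Band ranges are the
conventional clinical ones — theta 4–8, alpha 8–13, beta 13–30 Hz — which
the original description never fixes; they are echoed into every run
configuration.

In the default montage Pz and T4 are strongly emotion-dependent
(amplitudes, centre frequencies and chaos fraction all vary by class), T3
moderately so, and the remaining nine channels are identical across
emotions, so both informative and uninformative behaviour are represented.
Parameter values are plausible microvolt-scale EEG: calm is
alpha-dominant and regular, angry beta-dominant and irregular.

A second, feature-level generator (`simulate_feature_table()`) plants
class-dependent mean shifts directly into 12 of 27 feature columns,
leaving the rest standard normal. Its default spacing of 0.6 sd between
adjacent class means was calibrated once so that the dataset-averaged
class symmetric uncertainty of planted features falls in the 0.11–0.21
range that the bundled reference summary reports for its selected
features; it is the vehicle for selection-recovery experiments where the
identity of informative dimensions must be exact.

What the generator does *not* emulate: volume conduction and channel
correlations, ocular/muscle artifacts, 1/f background spectra,
non-stationarity within an epoch, and of course any genuinely
music-driven neural response. Passing recovery tests on these data shows
the pipeline's statistics behave as designed, not that real EEG carries
the planted structure.

## Preprocessing

*Epoch extraction* takes the centred window (0-based samples
\([\lfloor (T-E)/2 \rfloor f_s, \lfloor (T-E)/2 \rfloor f_s + E f_s)\)),
discarding onset and fatigue periods of a trial.

*Line suppression* is a fixed zero-phase IIR notch at 50 Hz: a biquad with
Q = 10 applied forward-backward twice. A single very narrow notch
(Q ≈ 30) attenuates more in steady state but rings up over several hundred
samples, leaking line power near the epoch edges; the wider cascade
reaches more than 30 dB of 50 Hz suppression on a 15 s epoch while
changing the 4–30 Hz passband by about 1% RMS at worst. Adaptive
reference-free line cancellation was considered and rejected: the contract
(notch depth, passband transparency) is identical and a fixed filter is
directly testable.

*Band decomposition* uses zero-phase 4th-order Butterworth bandpasses. At
\(f_s = 256\) Hz, dyadic wavelet-packet tiles are 4 Hz wide at depth 5 and
cannot represent the 8–13 Hz alpha band exactly, whereas IIR bands honour
the Hz boundaries; the decomposition is linear and time-aligned by
construction, which the tests assert.

*Optional denoising* is a periodic db4 pyramid with hard universal
thresholding (threshold \(\hat\sigma\sqrt{2\log n}\), \(\hat\sigma\) by
MAD of the finest details). Hard rather than soft thresholding: strong
oscillatory coefficients pass without shrinkage bias, which matters when
the signal of interest (e.g. an 8 Hz rhythm) lives in a detail band.

## Linear features (indices 1–18)

Per band signal: peak (signed maximum), sample mean, sample variance
(n−1 denominator; immaterial at n = 3840 but stated), centre frequency,
maximum power and power sum, in the canonical order alpha 1–6, theta
7–12, beta 13–18 (see `feature_dictionary()`).

The centre frequency uses the wavelet pseudo-frequency relation
\(F_a = F_c f_s / a\): a complex-Morlet (\(\omega_0 = 6\)) scale scan over
the band picks the scale with maximal response energy. This is the only
dimensionally consistent reading of the relation between scale and
frequency, and a pure tone is recovered to within 0.5 Hz.

The power features come from the spectrum of the biased autocorrelation
estimate, which equals the periodogram \(|X(\omega)|^2/N\) — computed that
way by FFT, guaranteeing a real non-negative spectrum on the full N-point
grid with exact Parseval consistency (grid mean = variance + squared
mean). Mean, variance and peak are computed on the band-filtered signals,
consistent with the per-band feature naming.

## Nonlinear features (indices 19–27)

Canonical order: singular spectral entropy, K entropy, approximate
entropy, maximum Lyapunov exponent, C0 complexity, sample entropy,
spectral entropy, Lempel–Ziv complexity, correlation dimension. The
estimators and their defaults (all exposed via `nonlinear_params()`):

| estimator | convention | defaults |
|---|---|---|
| ApEn | Pincus; Chebyshev distance, self-matches included | m = 2, r = 0.2 sd |
| SampEn | Richman–Moorman; self-matches excluded | m = 2, r = 0.2 sd; A = 0 maps to the sentinel \(\log((N-m)(N-m-1))\) |
| Correlation dimension | Grassberger–Procaccia, max-norm | embedding sweep m = 2..10, slope over the central 50% of the usable log-r span, saturation when successive slopes change < 0.1 |
| K entropy | GP correlation entropy K2 | ratio \(\ln(C_m/C_{m+1})/\tau\) over the same scaling region, m = 2 |
| Max Lyapunov | Rosenstein small-data | m = 3, Theiler window m·τ, slope of the initial linear region (ends at 90% of the total rise; whole-curve slope when total rise < 1 nat) |
| C0 | Fourier split into regular/irregular | coefficients with power > 5 × mean kept as "regular" |
| Singular spectral entropy | SVD of the L-lag trajectory matrix | L = 64, normalized by ln L |
| Spectral entropy | one-sided periodogram, DC excluded | normalized by ln(bins) |
| LZ complexity | LZ76 production count (Kaspar–Schuster) | median binarization, normalized c(n) log2(n)/n |

"K entropy" is implemented as the GP correlation entropy K2 — a lower
bound on the Kolmogorov–Sinai entropy — because true KS entropy is not
computable from data; K2 is the standard estimator in this family.

Delay choice: the template-match entropies use delay 1 (their standard
convention). The correlation-integral estimators and the Lyapunov
estimator use the first autocorrelation zero crossing, which makes the
embedded trajectory of an oscillation a proper circle (K2 of a sinusoid
then vanishes, as it must). One caveat found during validation and worth
recording: for the logistic *map* the theoretical autocorrelation is zero
at every lag, so a data-driven delay is finite-sample noise and can land
at 4–7, scrambling the embedding; map oracles are therefore evaluated at
delay 1, while EEG-like signals keep the data-driven rule.

Degenerate (zero-variance) inputs return 0 with a flag rather than
erroring, so batch extraction of a whole dataset never aborts. All nine
features are invariant under amplitude scaling because every tolerance is
sd-relative; the test suite asserts this for scalings 0.5, 2 and 10. The
shared O(N²) kernels (ApEn, SampEn, LZ76 parsing, correlation integrals,
neighbour divergence) are compiled (Rcpp); independent O(N²) brute-force
references written in plain R live in the test helpers and are held to
1e-10 agreement.

## Correlation-based feature selection

Eqs. of the CFS framework: entropy and conditional entropy in bits
(log2), information gain \(H(Y) - H(Y|X)\), symmetric uncertainty
\(U = 2\,\mathrm{gain}/(H(X)+H(Y)) \in [0,1]\), and the subset merit

\[
\mathrm{Merit}(s) = \frac{k\,\overline{r_{cf}}}{\sqrt{k + k(k-1)\,\overline{r_{ff}}}},
\]

with \(\overline{r_{cf}}\) the mean feature–class SU and
\(\overline{r_{ff}}\) the mean feature–feature SU over the k-subset (the
redundancy term vanishes at k = 1, where merit equals the class SU).
A worked consequence the tests encode: an exact duplicate of a feature
leaves merit unchanged (rff = 1 gives \(2u/\sqrt{4} = u\)) — redundancy
stops helping, it does not actively hurt in the k = 2 case.

Since the information measures need discrete variables and no
discretization is prescribed anywhere, equal-frequency binning with 5
bins is the default: with 80 trials that is 16 per bin, enough for stable
plug-in entropies at this sample size.

The search is the standard greedy forward CFS: the first feature maximizes
class SU, each later step adds the feature maximizing the augmented
subset's merit, ties break toward the lower canonical index so rankings
are fully deterministic. The greedy path never exceeds the exhaustive
optimum and attains it on most small tables (asserted against a
brute-force subset enumeration). Two selection summaries mirror the
reference reporting: the per-feature class SU averaged over datasets with
threshold 0.1, and top-10 selection-frequency counts over per-dataset,
per-stimulus-group (one-vs-rest) rankings with a "high" label above 20
counts — with 15 datasets × 4 groups = 60 rankings the reference counts
(up to 41) are only consistent with per-group counting, so that is the
default, switchable to per-dataset.

## Classifier verification

Four classifiers: SVM (RBF kernel, one-vs-one), a C4.5-style decision
tree (information-gain splits via rpart; exact Quinlan pruning and
fractional splits are not reproduced), a single-hidden-layer MLP
(2·inputs+1 units, weight decay), and LDA. None of their hyperparameters
were prescribed; the fixed defaults are recorded in the run config.

The cross-validation protocol description in the reference ("10% cross
validation, 10% of data is the training data … 100 times repetitions") is
self-contradictory; it is implemented as standard stratified 10-fold CV
repeated 10 times — 100 fold evaluations, the only reading consistent
with "cross validation" — with standardization parameters fit on training
folds only (a leakage canary test keeps this honest). The repeatability
protocol draws 8 random test trials per emotion (32 test, 72+ train) ten
times and reports per-repeat accuracies, which are therefore multiples of
100/32 = 3.125. LDA additionally drops columns that are (near-)constant
within groups before fitting — planted centre frequencies are effectively
discrete and would otherwise make the within-class covariance singular.

ROC curves are one-vs-rest with trapezoidal AUC (equivalently the rank
statistic), cross-checked against an independent ROC implementation in
the tests.

## Statistical reports

Paired t-tests per (electrode, emotion pair, dataset, feature), pairing
by within-dataset trial rank (no pairing rule is prescribed; rank pairing
is deterministic and order-respecting); cells count non-rejections
(p > 0.05), so with 27 features and 15 datasets a cell maxes at 405.
Zero-variance or numerically constant difference vectors have no defined
p and are counted as non-rejections, flagged. No multiple-testing
correction is applied by default, matching the raw counting convention;
Levene (mean- or median-centred, the latter the Brown–Forsythe form) and
classical one-way ANOVA utilities round out the reporting, implemented as
ANOVA on absolute deviations / group means over base `lm` and
cross-checked against independent implementations in the tests.

## Problem sizes and numerical choices in the shipped checks

The test-suite and the acceptance script exercise the pipeline at sizes
chosen to probe every claim while staying comfortably interactive: one
generated dataset of 80 trials with one informative (Pz) and one
uninformative (FP1) electrode at the full 15 s/256 Hz epoch for the
classifier-recovery checks; 50 replicate five-dataset studies of the
feature-level generator for selection recall; 3000-sample series for the
chaos oracles; and a two-dataset, 2 s-epoch configuration for the
byte-reproducibility check of the full pipeline. Correlation-integral
estimators cap their input at the leading 1200 samples (configurable), a
standard cost/variance compromise for O(N²) pair counts.

Seeds: every trial/channel seed derives deterministically from the master
`config$seed` by integer hashing below 2³¹, so any dataset, and the whole
pipeline, regenerates bit-identically.

## Known limitations

- The synthetic channels are mutually independent; no spatial structure
  or re-referencing effects exist, so cross-electrode analyses only probe
  bookkeeping, not physiology.
- The selected-feature reference set and the count/accuracy grids shipped
  under `inst/extdata/` are printed summaries used as *inputs* for
  arithmetic-reproduction checks; the package cannot (and does not claim
  to) reproduce the underlying recordings' headline recognition rates.
- K2 and the correlation dimension inherit the usual fragility of
  correlation-integral estimators on short or strongly oversampled
  series; their `low_confidence` flags should be honoured downstream.
- The C4.5-style tree is an information-gain CART, not a faithful Quinlan
  reimplementation.
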