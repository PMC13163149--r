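---
title: "Respiratory variability from accelerometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory variability from accelerometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respvar)
```

## The problem

In disorders of consciousness (DOC), behavioural scales such as the
Coma Recovery Scale–Revised (CRS-R, 0–23) are subjective and
examiner-dependent, while imaging and electrophysiology are hard to
deploy at the bedside. Breathing offers an accessible alternative
window on the central nervous system: respiratory rhythm is generated
in the brainstem and continuously modulated by autonomic and cortical
input, so the breath-to-breath variability (RV) of timing and depth
reflects the functional state of that network. `respvar` implements a
complete RV analysis for supine subjects instrumented with a single
abdominal accelerometer sampled at 10 Hz: signal conditioning, breath
segmentation, a time-domain RV metric suite over 300-s windows,
confounder-adjusted group comparison, and predictive modelling of
CRS-R scores and clinical improvement.

No public dataset of such recordings exists, so the package treats its
synthetic-data generator as a first-class module: it defines the study
conditions under which every downstream claim is tested.

## The synthetic generator

**Breath process.** Per-breath inspiratory time $T_i$, expiratory time
$T_e$ and amplitude each follow a stationary Gaussian AR(1) process
with marginal mean $\mu$, marginal SD $\sigma$ and lag-1
autocorrelation $\rho$:
$x_k = \mu + \rho\,(x_{k-1}-\mu) + \sigma\sqrt{1-\rho^2}\,\varepsilon_k$.
This is the simplest process with independently tunable mean, variance
and short-range correlation — the three properties the RV metrics are
designed to measure. Timing draws are floored at 0.3 s to keep breaths
physiological (the floor slightly biases means when $\sigma$ is a large
fraction of $\mu$; at the defaults the effect is negligible).
Defaults emulate quiet supine breathing: controls
$T_i$ 1.7 ± 0.15 s, $T_e$ 2.3 ± 0.2 s, $\rho = 0.3$ (≈ 15 breaths/min);
the patient arm carries larger timing SDs (0.32/0.42 s) and stronger
autocorrelation ($\rho = 0.6$), which elevates long-range variability
and in particular the I/E-ratio SD2 — the direction of group difference
the comparison stage is expected to detect. Between-subject
heterogeneity is multiplicative log-normal jitter (CV 0.15) on the
process parameters; without it every subject in an arm would be an
exact replicate and group tests would be degenerate.

**Waveform.** Each breath is rendered as a raised-cosine rise over
$T_i$ and fall over $T_e$, scaled by its amplitude — smooth, with
unambiguous extrema, and requiring no waveform database. The
one-dimensional waveform is projected onto three axes by a fixed unit
orientation vector (most power on z, as for a sensor taped flat on the
abdomen), then corrupted by a constant per-axis gravity offset, white
Gaussian noise, and a linear drift ramp. Amplitude is in arbitrary
acceleration units throughout: no tidal-volume calibration is implied,
and amplitude-derived metrics are used only in ratio or
within-cohort-comparison form.

**Recording SNR.** For a triaxial recording the signal-to-noise ratio
is defined as total respiratory signal power over total noise power
summed across the three channels (the standard multichannel
definition); `snr_noise_sd()` converts a target SNR in dB to the
per-axis noise SD. At the 10 dB level used in the recovery tests this
corresponds to a per-axis noise SD of about 6.5% of the breath
amplitude.

**Pathological patterns.** Biot's respiration — clusters of 3–5 normal
breaths alternating with apneic pauses of 10–30 s, per its clinical
description — exists to exercise quality control, as such recordings
must be excluded from RV analysis. Cheyne–Stokes (60-s waxing–waning
amplitude with nadir apneas) and ataxic breathing (tripled timing SDs,
no autocorrelation, random pauses) are provided for the same purpose.

**Clinical links.** Patient CRS-R scores are generated as a linear
function of the subject's *true* RV features plus Gaussian noise
(SD 2 score points), rounded and clamped to 0–23; improvement labels
are Bernoulli through a logistic link. The default links make higher
RV predict lower CRS-R and lower improvement probability — a
directional convention, not a claim about pathophysiology; both links
are fully configurable. With zero noise the latent CRS-R is exactly
linear in the features, which the tests exploit for calibration checks.

What the generator does *not* emulate: cardiac artifacts, sensor
quantization, Bluetooth dropouts, posture changes, or non-stationary
breathing within a recording. Passing tests therefore demonstrate that
the machinery is correct under the stated generative model, not that it
is robust to every artifact of real bedside data.

## Signal conditioning

The axis with maximal spectral power in the respiratory band is
selected and mean-removed; ties go to the lowest axis index. The band
is 0.1–0.7 Hz (6–42 breaths/min), spanning physiological supine rates;
the filter is an order-4 Butterworth applied forward and backward
(zero-phase), because Ti/Te derive from extremum times and any phase
shift would bias them. The input is padded by odd reflection before
filtering so start-up transients decay outside the data. A centred
0.5-s moving average (edge windows shrink rather than inventing
padding values) and a rolling-median baseline subtraction (20-s window,
interior estimate constant-extended over the outer half-windows)
complete the chain. The rolling median was chosen over polynomial
detrending because it is robust to apneic segments.

**Quality control** runs on the axis-selected, unfiltered signal. The
apnea fraction is the proportion of 5-s windows (50% overlap) whose
peak-to-peak excursion falls below 10% of the 90th-percentile window
amplitude — an upper-quantile reference that stays anchored to the
breathing amplitude even when most of the recording is apneic, and a
smoothed (not band-passed) working copy so that filter ringing cannot
fill the pauses. A recording is flagged as Biot-patterned when the
apnea fraction exceeds 0.2 *and* breathing resumes in two or more
distinct clusters; other flags are `too_short` (< 300 s) and `low_snr`
(spectral in-band SNR estimate < 3 dB). Flagged recordings are
excluded from downstream stages and logged, mirroring clinical
practice of excluding pathological respiratory patterns from RV
analysis. The thresholds are operational defaults exposed as arguments.

## Breath segmentation

Detection runs on the conditioned signal: local extrema are screened by
topographic prominence (≥ 0.3 × signal IQR) and a minimum same-type
separation of 1.5 s (a 40 breaths/min ceiling), then forced into strict
trough–peak alternation keeping the most extreme sample of any
same-type run.

Detected times are then *refined* on the raw axis signal. The flat
neighbourhood of a breathing extremum carries little timing
information, and band-pass filtering displaces the extrema of
asymmetric breaths by about one sample, so peak-picking alone cannot
reach sample-level accuracy in noise. Refinement therefore fits, for
each extremum, a local quadratic vertex (±0.5 s) followed by
coordinate-wise least-squares refits of each extremum's (time, value)
against a piecewise cosine half-wave model spanning its two
neighbours, iterated to convergence. Because each extremum's entire
contribution to the global residual lies between its neighbours, this
coordinate descent converges to a local optimum of the joint
piecewise-cosine fit, and it exploits the steep breath limbs — where
the timing information actually resides. The cosine segment model
matches the generator's rendered waveform; for other morphologies the
quadratic-only mode (`refine = "quadratic"`) avoids the template
assumption at the cost of timing precision. The two outermost extrema
on each side are dropped (they anchor the refinement one-sidedly and
sit in the filter's edge region), as are boundary partial breaths.

A breath is a trough–peak–trough triple: $T_i$ = peak − onset,
$T_e$ = offset − peak, rate = 60/$T_{tot}$, I/E ratio = $T_i/T_e$,
amplitude = peak minus trough value. Polarity is auto-detected: if the
rising limb is the longer one in the median breath the signal is taken
as inverted (inspiration is typically the shorter limb in quiet
breathing); an explicit override is available. Analysis windows keep
breaths whose onset falls within 300 s of the first complete breath.

## RV metrics

For each of the five per-breath series (rate, $T_i$, $T_e$, I/E ratio,
amplitude), seven metrics: sample SD (n − 1), CV = SD/mean, RMSSD
(root mean square of the n − 1 successive differences), triangular
index, and Poincaré SD1/SD2/ellipse area, for 35 features per subject.

The triangular index is series length divided by the modal histogram
count, with fixed-width bins anchored at zero: 0.1 s for $T_i$/$T_e$,
1 breath/min for rate, 0.05 for I/E ratio, and IQR/10 for amplitude
(whose units are arbitrary, so a fixed width would be meaningless).
The heart-rate-variability convention of 1/128-s bins does not
transfer to respiration's much slower time scale.

Poincaré descriptors use the population (n) SD of the rotated lag-1
coordinates $(x_k \mp x_{k+1})/\sqrt{2}$ — the convention under which
SD1 = RMSSD/$\sqrt2$ exactly when successive differences average zero —
while SD/CV use the sample (n − 1) convention. Ellipse area is
$\pi \cdot SD1 \cdot SD2$. "Respiratory-rate area" in this package
always means the Poincaré ellipse area of the rate series, the only
area-like quantity in the metric set.

## Group comparison

RV metrics are confounded by age, sex, body temperature, heart rate and
pulse pressure. Each metric is adjusted by a generalized additive
model with a smooth age term (thin-plate basis, dimension 5, smoothing
parameter by GCV) and linear terms for the remaining covariates. The
fitting population matters more than it first appears. Residualizing
against a model fitted on the pooled cohort *without* the group label
looks neutral, but when covariate distributions differ between arms —
and in the emulated cohort patients are older, warmer and
faster-hearted than controls — a genuine group effect has a nonzero
projection onto the covariates, and pooled-no-group residualization
silently removes that projection: in simulation roughly 40% of a
one-pooled-SD group effect, halving detection power. The default is
therefore ANCOVA-style: the GAM includes the group label, and the
adjusted value subtracts only the fitted covariate terms (recentred on
the pooled mean), so covariate effects are estimated without
omitted-variable bias and the group effect passes through intact.
Under null cohorts with a pure age effect this keeps the false
discovery fraction controlled while restoring power. The
pooled-no-group scheme remains available as
`gam_adjust(method = "pooled_nogroup")` for comparison. Subjects with
missing covariates are dropped per metric and logged.

Inference is deliberately split: the Mann–Whitney U test on adjusted
values supplies the p-value (RV metrics are routinely non-normal, which
the Shapiro–Wilk screen reports but does not act on), and the
within-group bootstrap (1000 resamples, shared resample indices across
metrics) supplies a 95% percentile CI for the patient-minus-control
median difference. Medians rather than means, for the same skewness
reason. The 35 p-values are corrected by Benjamini–Hochberg;
significance means q < 0.05. A `boot_stage` switch allows
bootstrapping before adjustment instead, since either ordering is
defensible; the default resamples adjusted values.

## Prediction

**CRS-R regression.** Random forest, elastic net, SVM-RFE (an RBF SVM
on features ranked by recursive elimination with a linear-SVM
surrogate — the standard construction) and PLS regression are compared
under nested cross-validation: outer 5-fold for error estimation,
inner 5-fold random search (default 50 draws; tests and the demo use
fewer) for tuning. MSE, RMSE, MAE and R² are computed on pooled
outer-fold predictions, so no tuning decision ever sees its own test
fold. Standardization statistics are computed on training folds only.

**Outcome classification.** Direct random forest, elastic-net-penalized
logistic selection followed by plain logistic regression, and
RF-permutation-importance top-k selection followed by logistic
regression, tuned by leave-one-out cross-validated AUC with random
search inside a stratified 70/30 training partition and evaluated on
the held-out 30% at a 0.5 threshold. The full ROC is reported so users
who weight sensitivity over specificity — the usual clinical stance in
DOC, where missing a potential improvement costs more than a false
alarm — can re-threshold. The 70/30 proportion is a choice; the
stratified-split and LOOCV structure are the method.

Covariates do not enter the predictive models by default (RV features
only); `build_matrix()` exposes the feature set explicitly so callers
can add them.

## Numerical choices and degenerate inputs

* Seeds: every stochastic routine takes an explicit seed; child seeds
  derive from a 32-bit LCG step so parallel subjects are decorrelated
  but reproducible. RNG state is saved and restored around all seeded
  code.
* Constant metric series: adjustment and Shapiro screening pass them
  through / report NA rather than erroring; CV errors only when the
  mean is exactly zero (undefined ratio).
* Tie-breaks: axis-selection ties go to x before y before z;
  feature-importance ties are broken by canonical feature-name order;
  the alternation filter keeps the most extreme sample.
* Bootstrap with B = 1 degenerates to a width-zero CI by construction.
* Exact Mann–Whitney null distribution for tie-free samples with
  min(n) ≤ 8; normal approximation with tie correction otherwise.

## Problem sizes

The shipped tests and the reproduction script use the following sizes,
chosen to estimate each property stably at desk scale: 44 subjects per
arm (the cohort scale the generator emulates); 200 replicate cohorts
for the type-I error of the comparison stage and 100 for its power;
50 seeds for breath-recovery accuracy at 10 dB SNR and for
quality-control flag rates; 20 seeds for the model-ordering and
label-permutation checks, with random-search budgets of 4–8 draws.

## Known limitations

* The cosine-template refinement is matched to the generator's
  waveform; on real data its benefit over the quadratic mode is an
  empirical question.
* At 10 Hz sampling and 10 dB per-axis SNR, extremum timing is
  information-limited: no estimator can localize $T_i$ much below
  ~0.14 s RMS from a single axis, which is why the multichannel SNR
  definition and the steep-limb fitting matter.
* The GAM adjustment assumes covariate effects are additive and
  group-independent; interactions between group and covariates are not
  modelled.
* Amplitude metrics are scale-arbitrary; only their dimensionless or
  within-cohort comparisons are meaningful.
* Time-domain metrics only; frequency-domain, fractal and entropy
  measures are out of scope.
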