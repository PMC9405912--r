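---
title: "EEG biomarkers of etiology and outcome in disorders of consciousness: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG biomarkers of etiology and outcome in disorders of consciousness: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

doceeg implements a complete analysis chain for resting-state clinical EEG
in patients with disorders of consciousness (DoC): from raw 19-channel
10-20 recordings to quantitative EEG (qEEG) and functional-connectivity
biomarkers, group-level biomarker screening, and leave-one-subject-out
(LOO) classification of six-month clinical outcome. A synthetic-cohort
generator with the same statistical structure stands in for clinical
recordings, so every stage is testable offline. This vignette records the
models, the parameters that matter, and the design decisions taken where
the underlying procedures were open.

## The analysis chain

**Preprocessing** (`standardize()`, `epoch_eeg()`, `reject_artifacts()`,
`detrend_epochs()`). Recordings are resampled to the analysis rate
(default 500 Hz; clinical source material is typically acquired at
1024 Hz) by exact spectral truncation, which is simultaneously an ideal
anti-alias filter, and bandpass filtered to 1--30 Hz. The bandpass is a
zero-phase spectral projection: the DFT is multiplied by a response that
is exactly 1 inside the band and 0 outside. Two consequences drive this
choice: phase is untouched (any phase distortion would bias the
phase-lag connectivity downstream), and the operation is idempotent --
re-filtering already-filtered data reproduces it to machine precision.
The cost is ringing near the recording ends, which the epoch-level
artefact rejection and per-epoch detrending absorb.

Artefact rejection is two-pass. Pass 1 drops epochs whose peak-to-peak
amplitude on any channel exceeds an absolute ceiling (default 500 µV).
Pass 2 targets statistically extreme epochs: each epoch is scored by its
largest absolute sample after per-channel scaling by the channel SD over
the currently kept epochs, and epochs whose score exceeds
`mean + 3 SD` of the score distribution are dropped, iterating to a
fixpoint (at most 8 iterations). The threshold is applied to an
*epoch-level* statistic rather than to raw samples: for approximately
Gaussian EEG, essentially every one-second epoch contains some sample
beyond 3 channel-SDs, so a per-sample rule would reject everything,
whereas the distribution of per-epoch extremes is tight and its 3-SD tail
isolates genuine excursions. This mirrors how automatic rejection is done
in practice (epoch statistics, iterated), and the exact rule is frozen in
the package and tested against a naive reimplementation. A degenerate
score distribution (e.g. identical epochs) rejects nothing. Every
rejection is logged with its pass and original epoch index; the kept mask
and the log always partition the original epochs.

Signals are cut into non-overlapping 1 s epochs for the spectral,
entropy, amplitude, mutual-information and coherence measures, and into
2 s epochs for the wavelet-based phase-lag index (longer epochs leave
usable data between the wavelet edge zones). Per epoch and channel the
least-squares line is removed.

**qEEG measures** (`compute_spectrum()`, `dominant_frequency()`,
`band_zpower()`, `permutation_entropy()`, `mean_amplitude()`).
The spectrum is the Hann-tapered periodogram averaged over epochs and
then electrodes, restricted to 1--30 Hz, scaled so the band-integrated
power approximates the in-band variance (Parseval). z-scoring is applied
across the retained frequency bins of the averaged spectrum: the original
description z-transforms the power without naming an axis, and the
across-bins reading makes the spectral shape -- hence the dominant
frequency and the band means -- invariant to overall signal scale, which
is the property the measures need. The dominant frequency is the location
of the global z-power maximum, ties resolved toward the lower frequency;
with 1 s epochs the resolution is 1 Hz. Band means use delta 1--3, theta
4--7, alpha 8--13, beta 14--30 Hz, with a bin on a shared edge assigned
to the lower band.

Permutation entropy uses ordinal patterns of order m = 3 with delay 1
(the source description fixes neither; order 3 at delay 1 is the common
default for short clinical epochs and both are configurable), pooled
over all kept epochs per electrode and normalised by log(3!) to [0, 1].
Ties break by order of occurrence. Mean amplitude is the mean *absolute*
value of the detrended signal: the plain mean of a detrended trace is
zero by construction, so the absolute value is what carries the
amplitude information.

**Connectivity** (`laplacian_filter()`, `morlet_tf()`, `wpli_matrix()`,
`wpli_threshold()`, `coherence_matrix()`,
`mutual_information_matrix()`, `roi_summarize()`). All three estimators
run on surface-Laplacian referenced signals: each electrode minus the
mean of its nearest neighbours on the 10-20 layout
(`laplacian_neighbors()` ships the versioned map), which suppresses
volume-conducted common sources. The weighted phase lag index of a pair
is `|mean(Im S)| / mean(|Im S|)` with `S` the cross-spectrum of the
complex Morlet analytic signals at the subject's dominant frequency,
pooled over epochs and retained time samples; it is 0 by convention when
the denominator vanishes (strictly zero-lag coupling) and discounts
zero-lag interactions by construction. The wavelet has 6 cycles
(unspecified in the source; 6 is the common compromise between time and
frequency resolution), is applied by frequency-domain multiplication,
and samples within 2.5 temporal SDs of an epoch edge are excluded.
Because the analytic signal is band-limited to the wavelet bandwidth,
pooling uses about four samples per cycle of the analysis frequency;
the decimated and full evaluations agree to ~1e-11 and the naive-oracle
tests apply the same declared definition. In the pipeline the analysis
frequency is clamped to [3, 30] Hz: below 3 Hz a 6-cycle wavelet does
not fit a 2 s epoch.

Each subject receives a wPLI threshold from surrogate data: every
channel's analytic signal is independently circularly time-shifted
within each epoch (spectra preserved, cross-channel phase relations
destroyed), the wPLI recomputed (default 200 surrogates), and pair
values below the 95th percentile of their own surrogate distribution set
to zero. Circular shifts were chosen over phase randomisation because
they preserve the full within-channel structure exactly and are cheap to
iterate.

Coherence is magnitude-squared coherence from epoch-averaged cross- and
auto-spectra. The "partial" character of the published measure is
supplied by the Laplacian reference (the cited routine computes
cross-coherence; what was partialled out is not stated -- this is logged
as an open question), and an FDR-based significance mask over the 171
pairs is available separately without ever altering point estimates. The
primary reading averages coherence over the full 1--30 Hz band (no
padding needed for a band average); the dominant-frequency reading uses
zero padding with pad ratio 8 (0.125 Hz grid at 1 s epochs) as
specified for that variant.

Mutual information uses amplitude histograms with 10 equal-width bins
spanning each channel's observed range, `MI = H(X) + H(Y) - H(X, Y)` in
bits. The fixed 10 bins follow the published setting; a
Freedman--Diaconis-derived count (`fd_bin_count()`) is available since
the rule is invoked alongside the fixed count. Equal-width bins over the
observed range make MI exactly invariant to channel-wise rescaling. A
constant channel yields MI 0 with a warning.

The 19x19 matrices are summarised into five regions of interest. The
source names the ROIs but not their electrodes; the package declares a
standard hemispheric split (configurable): left frontoparietal
{Fp1,F3,F7}x{P3,T5}, right frontoparietal {Fp2,F4,F8}x{P4,T6}, frontal
interhemispheric {Fp1,F3,F7}x{Fp2,F4,F8}, central interhemispheric
{T3,C3}x{C4,T4}, posterior interhemispheric {P3,T5,O1}x{P4,T6,O2};
midline electrodes are excluded. The ROI value is the mean over its
pairs and the global value the mean of the five ROI values.

**Screening** (`screen_biomarkers()`, `mixed_anova()`,
`bootstrap_ttest()`). Each connectivity estimator enters a mixed
ANOVA/ANCOVA with the between-subject factor (etiology or outcome) and
the within-subject ROI factor (5 levels); scalar qEEG measures enter a
one-way (An)cova. Models are fitted as multivariate linear models with
Type III sums of squares (the common statistical-software default for
unbalanced groups); within-subject effects carry Greenhouse--Geisser
corrected degrees of freedom and p-values, and partial eta squared is
`F*df1 / (F*df1 + df2)` on the reported degrees of freedom. Age is the
default covariate for the etiology factor (the etiological groups differ
in age); outcome analyses are unadjusted by default with GCS/GOS
covariates available. Planned contrasts use a two-sided bootstrap
t-test: the pooled-variance t statistic is recomputed on 1000
within-group resamples drawn under the null (groups recentred to the
grand mean), with a percentile CI for the raw difference also reported
-- the published phrase "bootstrap corrections" is ambiguous between a
bootstrap p and a bootstrap CI, so both are emitted. A measure is
"selected" when its group effect is significant at alpha = 0.05, with no
multiple-testing correction across the family, matching the screening
design. All reported p-values are two-tailed; for a directional
single-df contrast (as used in the source for the dominant-frequency
analysis) the one-tailed reading is half the reported p.

**Classification** (`lda_loo()`, `stepwise_search()`,
`logistic_loo()`). The classifier is a diagonal-covariance linear
discriminant: classes share one diagonal covariance, so feature
correlations are fully discounted (the published setting: diagLinear
with full shrinkage and no coefficient thresholding), with priors equal
to training-fold class frequencies. Validation is leave-one-subject-out
with feature standardisation recomputed inside every training fold (no
leakage; diagonal LDA is additionally invariant to per-feature affine
rescaling, which the tests verify). "Stepwise" selection is implemented
as exhaustive search over all non-empty subsets of the (at most 10,
typically 4) candidate features, because the published results describe
measures "taken alone or in conjunction"; a greedy forward mode exists
for larger pools. Ties rank by balanced accuracy, then fewer features,
then lexicographic order. The positive class is the *nonimproved*
outcome (the published sensitivity is the rate of correctly identified
nonimproved patients); accuracy, sensitivity, specificity, balanced
accuracy and precision come from the pooled LOO confusion matrix, and
the ROC sweeps the pooled discriminant-score threshold. A multivariate
logistic regression run under the identical protocol serves as a
control; a training fold with perfect separation falls back to a
ridge-penalised fit (penalty 1e-4) with a logged warning. Classification
runs separately per etiology stratum; a stratum needs at least 4
subjects and 3 per outcome class or it is skipped with a notice.

## The synthetic cohort: what it emulates, and what it does not

`generate_subject_eeg()` builds each recording from four components, all
in microvolts at the recording rate:

* per-channel 1/f background noise, amplitude spectrum proportional to
  `(1 + f)^(-1/2)`, SD 20 µV x `noise_gain`;
* a narrowband Gaussian oscillator (bandwidth 0.5 Hz) at the subject's
  dominant frequency on every channel, SD 15 µV -- strong enough that
  the z-scored spectral peak beats the 1/f rise at the band edge, as in
  the delta/theta-dominant spectra of DoC patients;
* lagged phase coupling: on five designated pairs (one inside each ROI),
  the receiver's oscillator is the convex mixture
  `(1 - c) * own + c * lagged copy of the sender`, the lag a quarter
  cycle at the dominant frequency. At `c = 1` the pair phase difference
  is constant and non-zero, so the wPLI approaches 1; at `c = 0` pairs
  are independent and sit at the estimator's null baseline. A zero-lag
  mixing mode provides the volume-conduction control;
* three zero-lag broadband shared sources, each with an independent
  signed Gaussian topography over the channels and SD
  8 µV x `shared_source_gain`. Signed random topographies survive the
  Laplacian (a uniform topography would be subtracted away) and drive
  mutual information and coherence without moving the wPLI, which
  discounts zero-lag mixing -- this keeps the etiology-linked and
  outcome-linked effects separable by construction;
* optional artefacts: square pulse plus drift excursions at 6x the
  background SD on four random channels of randomly selected one-second
  segments, sized to be caught by the rejection stage.

`generate_cohort()` draws subject parameters around group means. The
emulated cohort is 15 TBI / 18 non-TBI with 8 and 5 improved subjects
respectively; ages follow the published group means (34.3 vs 49.1
years). Group effects follow the published directions -- TBI slower
dominant frequency and weaker lagged coupling; improved outcome stronger
shared sources -- with defaults of about 1.7 between-subject SDs
(dominant frequency 4.0 vs 6.0 Hz, SD 1.2; coupling 0.35 vs 0.55, SD
0.12; shared gain 0.75 vs 1.5, SD 0.25). The magnitudes are a design
choice made once: no quantitative SNR or effect-size information about
the clinical recordings is available, and the replication property is
meant to test the pipeline's mechanics at the study's n = 33, not to
re-estimate clinical power. GOS scores are assigned consistently with
the outcome label (improved if and only if the six-month GOS exceeds
the one-month GOS by at least 1).

What the generator does **not** emulate: biophysical head geometry and
realistic volume conduction, lesion-dependent topographies, reactivity
or evoked activity, non-stationarity over a 20-minute session, and
realistic artefact morphology beyond amplitude excursions. Passing tests
therefore demonstrate that the estimators, screening and classification
recover known injected structure through the full pipeline -- not that
the clinical effect sizes themselves are reproducible from this package.

## Numerical choices and degenerate inputs

* FFT-based resampling and filtering are exact (circular) spectral
  operations; the 1024 to 500 Hz ratio is non-integer, so sample counts
  are contract-checked to +-1.
* wPLI returns 0 when `mean(|Im S|) = 0`; MI is clipped at 0 against
  rounding; coherence is clipped to [0, 1].
* The wPLI surrogate threshold is the per-pair 95th percentile
  (interpolating type-7 quantile) of at least 20 surrogates;
  thresholding is deterministic given the seed.
* Permutation-entropy ties break by order of occurrence (strictly-less
  comparisons on later elements).
* Empty-after-rejection is an explicit error, never a silent pass-through;
  single-class classification input is an explicit error; a class with
  fewer than 2 training members in any LOO fold is an explicit error.
* All simulation seeds derive from one master seed; per-subject seeds are
  drawn once at cohort generation, and seeded helpers restore the
  caller's RNG state.

## Problem sizes used by the test and acceptance studies

Simulation studies run on 33-subject cohorts with 60 s recordings
sampled at 250 Hz and 50 wPLI surrogates: the analyses are band-limited
to 30 Hz, so 250 Hz carries the full information of the 500 Hz analysis
rate for synthetic data, and 60 s of clean signal is ample for
estimators whose within-subject variance is dominated by epoch counts.
The selection-pattern study uses 50 replicate cohorts; the type-I
screening study uses 50 null cohorts at 30 s (type-I control does not
depend on recording length); calibration studies use 2000 bootstrap and
1000 mixed-ANOVA null replicates. Clinical-scale runs (20-minute
recordings at 500 Hz, 200 surrogates) use the same code paths through
`pipeline_config()` defaults.

## Known limitations

* The rejection rule is a declared stand-in for the original automatic
  routine, whose internals (iteration caps, amplitude criteria) are not
  published; no bit-equivalence is claimed.
* The ROI electrode sets and the Laplacian adjacency are declared,
  versioned conventions, not published tables.
* The meaning of "partial" in the published coherence and the pooling
  axis of the published wPLI are unresolved in the source; the package's
  conventions (Laplacian-referenced pairwise coherence; pooling over
  epochs and retained samples) are documented above.
* Printed Cohen's d values in the source are not reproducible from its
  own summary tables under any standard formula; d is reported by the
  package but never used as an acceptance surface.
* The dominant frequency inherits the 1 Hz resolution of 1 s epochs;
  subjects near a bin edge can flip bins across noise realisations.
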