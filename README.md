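# doceeg

Resting-state EEG biomarkers of etiology and outcome in disorders of
consciousness (DoC).

After severe acquired brain injury, patients in an unresponsive
wakefulness syndrome or minimally conscious state are hard to prognose
from behavioural scales alone. Standard clinical EEG — 19 electrodes in
the 10–20 montage, eyes-closed rest — is available almost everywhere, and
quantitative descriptors of it carry prognostic signal. `doceeg`
implements, as a tested R package, the full analysis chain for such
studies:

1. **Preprocessing**: resampling to the analysis rate, zero-phase 1–30 Hz
   bandpass, 1 s re-epoching, two-pass automatic artefact rejection with
   an auditable log, linear detrending (`preprocess_recording()`).
2. **qEEG measures**: z-scored power spectral density per band (delta
   1–3, theta 4–7, alpha 8–13, beta 14–30 Hz), dominant frequency,
   permutation entropy (order 3), mean absolute amplitude
   (`qeeg_features()`).
3. **Functional connectivity** on surface-Laplacian referenced signals,
   as 19×19 matrices summarised into five regions of interest (left/right
   frontoparietal, frontal/central/posterior interhemispheric) and a
   global mean (`roi_summarize()`):
   - weighted phase lag index at the individual dominant frequency, from
     complex Morlet time–frequency data on 2 s epochs, with a per-subject
     surrogate threshold, `wPLI = |E[Im S]| / E[|Im S|]`
     (`wpli_threshold()`);
   - magnitude coherence from epoch-averaged cross-spectra, on the full
     signal and at the dominant frequency with pad ratio 8
     (`coherence_matrix()`);
   - histogram mutual information, 10 bins,
     `MI = H(X) + H(Y) − H(X,Y)` in bits
     (`mutual_information_matrix()`).
4. **Biomarker screening**: mixed ANOVA/ANCOVA with the within-subject
   ROI factor and Greenhouse–Geisser correction, partial eta squared,
   bootstrap t-tests, Shapiro–Wilk and Mann–Whitney utilities
   (`screen_biomarkers()`, `mixed_anova()`, `bootstrap_ttest()`).
5. **Outcome classification**: stepwise (exhaustive-subset)
   diagonal-covariance LDA with leave-one-subject-out cross-validation,
   per etiology stratum, positive class = nonimproved, with a logistic
   regression control and full metric/ROC reporting (`stepwise_search()`,
   `lda_loo()`, `logistic_loo()`).
6. **Synthetic cohorts**: `generate_cohort()` builds 19-channel
   recordings with a controllable spectral peak, quarter-cycle lagged
   phase coupling (drives the wPLI), zero-lag broadband shared sources
   with subject-specific topographies (drive MI and coherence without
   moving the wPLI), 1/f background, artefact excursions, and
   etiology/outcome group effects in the directions reported for the
   clinical cohort — so the whole chain is testable without clinical
   data. EDF import/export and a cohort CSV round-trip are included.

Results come back as tibbles or as small S3 objects with `tidy()`,
`glance()` and `autoplot()` methods, so they drop straight into dplyr /
ggplot2 workflows. `run_pipeline()` orchestrates the end-to-end study and
writes versioned outputs (`features.csv`, per-subject matrices, JSON
reports, provenance); `exec/doc-eeg` is a thin command-line front end
(`doc-eeg simulate | run-all | classify`).

## Worked example

Reconstructing the published between-group statistics from the cohort
summary table (group means with standard errors):

```r
library(doceeg)

# age: non-TBI 49.1 (SE 3.59, n = 18) vs TBI 34.3 (SE 4.4, n = 15)
pooled_t_from_summary(49.1, 3.59, 18, 34.3, 4.4, 15)
#> # A tibble: 1 × 3
#>       t    df      p
#>   <dbl> <dbl>  <dbl>
#> 1  2.63    31 0.0131

partial_eta_sq(6.862, 1, 30)    # wPLI etiology effect, F(1,30)
#> [1] 0.1861538

metrics_from_rates(0.923, 0.600, 13, 5)   # non-TBI confusion rates
#> # A tibble: 1 × 3
#>   accuracy balanced_accuracy precision
#>      <dbl>             <dbl>     <dbl>
#> 1    0.833             0.762     0.857
```

So the published age contrast (t(31) = 2.62), the wPLI etiology effect
size (ηp² = 0.186) and the non-TBI classification metrics (accuracy
83.3%, precision 85.7%) all fall out of the printed summaries.

Running the full pipeline on a synthetic 33-subject cohort (60 s
recordings, 250 Hz, 50 surrogates — the simulation-study problem size):

```r
cfg <- pipeline_config(
  cohort = cohort_config(recording_length_s = 60, sampling_rate_hz = 250,
                         master_seed = 7),
  target_rate_hz = 250, n_surrogates = 50, master_seed = 7
)
run <- run_pipeline(cfg)
run
#> <doc_run> 33 subjects (synthetic input), seed 7
#> etiology biomarkers: dominant_freq_hz, zpsd_delta, zpsd_theta, zpsd_beta, peen_mean
#> outcome biomarkers: amp_mean_uv, wpli, pcoh, mi
#> TBI: best {pcoh_global}, LOO accuracy 93.3%
#> nonTBI: best {mi_global}, LOO accuracy 83.3%

run$classification$nonTBI$lda
#> <doc_classifier> diag-LDA on {mi_global}, positive = nonimproved
#>              truth
#> predicted     nonimproved improved
#>   nonimproved          11        2
#>   improved              1        4
#> accuracy 83.3% | sensitivity 84.6% | specificity 80.0% | balanced 82.3% | precision 91.7%
```

The screening stage picks up the injected group structure (slower
dominant frequency in TBI; stronger shared-source connectivity in
improved patients), and the stepwise LDA finds a connectivity feature
that separates outcomes within each etiology stratum. Any single cohort
is noisy at n = 33 — the acceptance analysis below averages the
selection pattern over 50 replicate cohorts.

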