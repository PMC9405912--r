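test_that("same seed gives bit-identical recordings, different seeds differ", {
  p <- subject_profile(seed = 99, artefact_rate = 0.1)
  r1 <- generate_subject_eeg(p, 20, 250)
  r2 <- generate_subject_eeg(p, 20, 250)
  expect_identical(r1$data, r2$data)
  p2 <- subject_profile(seed = 100, artefact_rate = 0.1)
  expect_false(identical(generate_subject_eeg(p2, 20, 250)$data, r1$data))
})

test_that("profile validation rejects out-of-range parameters", {
  expect_error(subject_profile(dominant_freq_hz = 0.5), "1-30")
  expect_error(subject_profile(coupling_strength = 1.2), "\\[0, 1\\]")
  expect_error(subject_profile(noise_gain = 0), "positive")
  expect_error(generate_subject_eeg(subject_profile(), 10, -1), "positive")
})

test_that("an injected spectral peak is recovered by the spectral module", {
  p <- subject_profile(dominant_freq_hz = 10, coupling_strength = 0,
                       shared_source_gain = 0, seed = 5)
  rec <- generate_subject_eeg(p, 30, 250)
  ep <- preprocess_recording(rec, target_rate_hz = 250)
  f0 <- dominant_frequency(compute_spectrum(ep))
  expect_lte(abs(f0 - 10), 1) # within one 1 Hz bin
})

test_that("injected dominant frequency is recovered across seeds", {
  hits <- vapply(1:20, function(s) {
    f_true <- 4 + (s %% 7) # 4..10 Hz
    p <- subject_profile(dominant_freq_hz = f_true, coupling_strength = 0,
                         shared_source_gain = 0, seed = 300 + s)
    ep <- preprocess_recording(generate_subject_eeg(p, 20, 250),
                               target_rate_hz = 250)
    abs(dominant_frequency(compute_spectrum(ep)) - f_true) <= 1
  }, logical(1))
  expect_true(all(hits))
})

test_that("full lagged coupling drives the pair wPLI towards 1", {
  vals <- vapply(1:5, function(s) {
    p <- subject_profile(dominant_freq_hz = 8, coupling_strength = 1,
                         shared_source_gain = 0, seed = 40 + s)
    rec <- generate_subject_eeg(p, 30, 250)
    ep2 <- preprocess_recording(rec, target_rate_hz = 250, epoch_length_s = 2)
    w <- wpli_matrix(morlet_tf(ep2, 8))
    w$values["F3", "P3"]
  }, numeric(1))
  expect_true(all(vals >= 0.9))
})

test_that("uncoupled cohorts sit at the wPLI null baseline", {
  # with no coupling and no shared source, almost all pairs must fall below
  # their per-subject surrogate threshold
  frac_surviving <- vapply(1:6, function(s) {
    p <- subject_profile(dominant_freq_hz = 7, coupling_strength = 0,
                         shared_source_gain = 0, seed = 60 + s)
    rec <- generate_subject_eeg(p, 30, 250)
    ep2 <- preprocess_recording(rec, target_rate_hz = 250, epoch_length_s = 2)
    wt <- wpli_threshold(ep2, 7, n_surrogates = 50, seed = s)
    mean(wt$values[upper.tri(wt$values)] > 0)
  }, numeric(1))
  expect_lt(mean(frac_surviving), 0.10)
})

test_that("estimated wPLI rises monotonically with coupling strength", {
  strengths <- c(0, 0.25, 0.5, 0.75, 1)
  mean_wpli <- vapply(strengths, function(cs) {
    mean(vapply(1:20, function(s) {
      p <- subject_profile(dominant_freq_hz = 8, coupling_strength = cs,
                           shared_source_gain = 0, seed = 700 + s)
      rec <- generate_subject_eeg(p, 20, 250)
      ep2 <- preprocess_recording(rec, target_rate_hz = 250,
                                  epoch_length_s = 2)
      w <- wpli_matrix(morlet_tf(ep2, 8))
      pairs <- default_coupled_pairs()
      mean(w$values[pairs])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_wpli) > 0))
})

test_that("cohort generation reproduces the clinical group structure", {
  cfg <- cohort_config(n_tbi = 15, n_nontbi = 18, recording_length_s = 10,
                       master_seed = 4)
  gen <- generate_cohort(cfg)
  expect_equal(nrow(gen$cohort), 33)
  expect_equal(sum(gen$cohort$etiology == "TBI"), 15)
  expect_equal(sum(gen$cohort$outcome == "improved" &
                     gen$cohort$etiology == "TBI"), 8)
  expect_equal(sum(gen$cohort$outcome == "improved" &
                     gen$cohort$etiology == "nonTBI"), 5)
  # outcome label and GOS scores are mutually consistent
  expect_equal(gen$cohort$outcome,
               outcome_from_gos(gen$cohort$gos_t0, gen$cohort$gos_t1))
  # reproducible from the master seed
  gen2 <- generate_cohort(cfg)
  expect_identical(gen$cohort, gen2$cohort)
  # injected effect directions
  with(gen$cohort, {
    expect_gt(mean(gen_dominant_freq_hz[etiology == "nonTBI"]),
              mean(gen_dominant_freq_hz[etiology == "TBI"]))
    expect_gt(mean(gen_shared_source_gain[outcome == "improved"]),
              mean(gen_shared_source_gain[outcome == "nonimproved"]))
  })
})

test_that("degenerate single-class cohorts are refused by the classifier", {
  cfg <- cohort_config(n_tbi = 4, n_nontbi = 4, improved_fraction = 0,
                       effects = null_effects(), recording_length_s = 10,
                       master_seed = 9)
  gen <- generate_cohort(cfg)
  expect_true(all(gen$cohort$outcome == "nonimproved"))
  dat <- dplyr::mutate(gen$cohort, f1 = gen_noise_gain)
  expect_error(lda_loo(dat, "f1"), "both outcome classes")
})

test_that("null cohorts keep per-measure screening type-I control", {
  # all effect shifts zero: each candidate biomarker may be selected in at
  # most ~alpha of replicate cohorts (binomial slack at 50 replicates)
  cfg <- pipeline_config(
    cohort = cohort_config(effects = null_effects(), recording_length_s = 30,
                           sampling_rate_hz = 250, master_seed = 1L),
    target_rate_hz = 250, n_surrogates = 20
  )
  sim <- suppressWarnings(
    simulate_screening_study(n_cohorts = 50, config = cfg, seed = 401)
  )
  sel <- dplyr::summarise(
    dplyr::group_by(sim$selection, .data$factor, .data$measure),
    rate = mean(.data$selected), .groups = "drop"
  )
  for (msr in c("dominant_freq_hz", "wpli", "mi", "pcoh")) {
    for (fac in c("etiology", "outcome")) {
      expect_lte(sel$rate[sel$factor == fac & sel$measure == msr], 7 / 50)
    }
  }
})

test_that("cohort EDF export writes one file per subject plus the table", {
  cfg <- cohort_config(n_tbi = 2, n_nontbi = 2, recording_length_s = 4,
                       sampling_rate_hz = 100, master_seed = 2)
  gen <- generate_cohort(cfg, keep_recordings = TRUE)
  dir <- withr::local_tempdir()
  write_cohort_edf(gen, dir)
  expect_length(list.files(dir, pattern = "\\.edf$"), 4)
  tb <- read.csv(file.path(dir, "cohort.csv"))
  expect_equal(names(tb), c("subject_id", "etiology", "age_years",
                            "gcs_baseline", "gos_t0", "gos_t1"))
  back <- read_edf(file.path(dir, paste0(gen$cohort$subject_id[1], ".edf")))
  expect_equal(back$sampling_rate_hz, 100)
})
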