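test_that("surface Laplacian removes common-mode and localises sources", {
  common <- make_epochs(array(rep(sin(1:100), each = 2 * 19), c(2, 19, 100)),
                        100, ch19)
  out <- laplacian_filter(common)
  expect_lt(max(abs(out$data)), 1e-9)

  # signal on Cz only: Cz unchanged, each neighbour gets -1/k of it
  arr <- array(0, c(1, 19, 100))
  cz <- match("Cz", ch19)
  arr[1, cz, ] <- sin(1:100)
  out2 <- laplacian_filter(make_epochs(arr, 100, ch19))
  expect_equal(out2$data[1, cz, ], sin(1:100))
  nb <- laplacian_neighbors()
  c3 <- match("C3", ch19) # C3 has 4 neighbours; Cz is one of them
  expect_equal(out2$data[1, c3, ], -sin(1:100) / length(nb$C3))
  untouched <- match("O1", ch19)
  expect_equal(out2$data[1, untouched, ], rep(0, 100))

  expect_error(laplacian_filter(common, neighbors = nb[-1]), "cover every")
})

test_that("Morlet analytic signal has the right phase velocity and gain", {
  fs <- 250
  rec <- make_recording(20, fs, function(t, ci) 3 * sin(2 * pi * 10 * t))
  ep <- epoch_eeg(rec, 2)
  tf <- morlet_tf(ep, 10)
  z <- tf$tf[1, 1, tf$retained]
  dphi <- diff(Arg(z))
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dphi - 2 * pi * 10 / fs)) / (2 * pi * 10 / fs), 0.01)
  # modulus constant and proportional to amplitude
  expect_lt(sd(Mod(z)) / mean(Mod(z)), 0.01)
  rec2 <- make_recording(20, fs, function(t, ci) 6 * sin(2 * pi * 10 * t))
  z2 <- morlet_tf(epoch_eeg(rec2, 2), 10)$tf[1, 1, tf$retained]
  expect_equal(mean(Mod(z2)) / mean(Mod(z)), 2, tolerance = 1e-6)
})

test_that("off-frequency attenuation follows the Gaussian spectral window", {
  fs <- 250
  f0 <- 15
  rec_on <- make_recording(20, fs, function(t, ci) sin(2 * pi * f0 * t))
  rec_off <- make_recording(20, fs, function(t, ci) sin(2 * pi * (f0 + 10) * t))
  tf_on <- morlet_tf(epoch_eeg(rec_on, 2), f0)
  tf_off <- morlet_tf(epoch_eeg(rec_off, 2), f0)
  gain <- mean(Mod(tf_off$tf[1, 1, tf_off$retained])) /
    mean(Mod(tf_on$tf[1, 1, tf_on$retained]))
  sigma_f <- f0 / 6
  expect_equal(gain, exp(-10^2 / (2 * sigma_f^2)), tolerance = 0.02)
  expect_error(morlet_tf(epoch_eeg(rec_on, 2), 1), "wavelet longer")
})

test_that("wPLI reaches its analytic limits", {
  fs <- 250
  set.seed(51)
  # constant quarter-cycle lag plus light independent jitter
  rec <- make_recording(60, fs, function(t, ci) {
    ph <- if (ci == 2) -pi / 2 else 0
    20 * sin(2 * pi * 8 * t + ph) + rnorm(length(t), sd = 0.5)
  })
  tf <- morlet_tf(epoch_eeg(rec, 2), 8)
  w <- wpli_matrix(tf)
  expect_gte(w$values[1, 2], 0.98)
  expect_true(all(w$values >= 0 & w$values <= 1))
  expect_equal(w$values, t(w$values))
  expect_true(all(diag(w$values) == 0))

  # zero-lag identical channels: Im S = 0 everywhere, guarded to 0
  rec_same <- make_recording(60, fs, function(t, ci) sin(2 * pi * 8 * t))
  w0 <- wpli_matrix(morlet_tf(epoch_eeg(rec_same, 2), 8))
  expect_equal(w0$values[1, 2], 0)
  expect_error(wpli_matrix(morlet_tf(epoch_eeg(make_recording(10, fs), 2), 8)),
               "at least 10 epochs")
})

test_that("connectivity estimators match naive oracles on a small fixture", {
  # 4 channels x 20 epochs of 2 s; mixture of oscillations and noise
  fs <- 125
  set.seed(52)
  n_ep <- 20
  ns <- 250
  arr <- array(0, c(n_ep, 4, ns))
  t <- seq_len(ns) / fs
  for (e in seq_len(n_ep)) {
    base <- sin(2 * pi * 9 * t + e)
    arr[e, 1, ] <- 10 * base + rnorm(ns)
    arr[e, 2, ] <- 6 * sin(2 * pi * 9 * t + e - 1.1) + rnorm(ns)
    arr[e, 3, ] <- 4 * base + 8 * rnorm(ns)
    arr[e, 4, ] <- rnorm(ns)
  }
  labs <- c("F3", "C3", "P3", "O1")
  ep <- make_epochs(arr, fs, labs)

  # wPLI: package (FFT-based TF, compiled accumulation) vs direct DFT +
  # per-pair loops
  tf <- morlet_tf(ep, 9)
  step <- max(1L, round(fs / (4 * 9)))
  idx <- tf$retained[seq(1, length(tf$retained), by = step)]
  w_pkg <- wpli_matrix(tf)
  z_or <- lapply(1:4, function(ci) {
    unlist(lapply(seq_len(n_ep), function(e) {
      oracle_morlet(arr[e, ci, ], fs, 9)[idx]
    }))
  })
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(w_pkg$values[i, j], oracle_wpli_pair(z_or[[i]], z_or[[j]]),
                   tolerance = 1e-9)
    }
  }

  # coherence (full band, pad 2) vs naive epoch-wise DFT
  coh_pkg <- coherence_matrix(ep, "full_band", pad_ratio = 2)
  nfft <- ns * 2
  bins_hz <- ((seq_len(nfft) - 1) * fs / nfft)
  bins_hz <- bins_hz[bins_hz >= 1 - 1e-9 & bins_hz <= 30 + 1e-9]
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(coh_pkg$values[i, j],
                   oracle_coherence_pair(arr[, i, ], arr[, j, ], fs,
                                         bins_hz, 2),
                   tolerance = 1e-9)
    }
  }

  # mutual information vs naive histogram counting
  mi_pkg <- mutual_information_matrix(ep)
  flat <- doceeg:::concat_epochs(ep)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(mi_pkg$values[i, j],
                   oracle_mi_pair(flat[i, ], flat[j, ]), tolerance = 1e-9)
    }
  }

  # Laplacian vs explicit loops (on the 19-channel montage)
  set.seed(53)
  arr19 <- array(rnorm(3 * 19 * 100), c(3, 19, 100))
  ep19 <- make_epochs(arr19, 100, ch19)
  expect_equal(laplacian_filter(ep19)$data,
               oracle_laplacian(arr19, ch19, laplacian_neighbors()),
               tolerance = 1e-9)

  # ROI means vs explicit pair loops
  set.seed(54)
  m <- matrix(rnorm(19 * 19), 19, 19)
  m <- (m + t(m)) / 2
  cm <- connectivity_matrix(m, estimator = "MI")
  got <- roi_summarize(cm)
  want <- oracle_roi(cm$values, ch19, roi_pairs())
  expect_equal(unlist(got[doceeg:::roi_names()]), want[doceeg:::roi_names()],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(got$global_mean, unname(want["global"]), tolerance = 1e-9)
})

test_that("surrogate thresholding controls false positives and keeps truth", {
  fs <- 250
  survived_null <- vapply(1:8, function(s) {
    ep <- noise_epochs(15, 6, 2 * fs, fs, seed = 500 + s,
                       labels = ch19[1:6])
    wt <- wpli_threshold(ep, 8, n_surrogates = 60, alpha = 0.05, seed = s)
    mean(wt$values[upper.tri(wt$values)] > 0)
  }, numeric(1))
  expect_lte(mean(survived_null), 0.05 + 0.05)

  kept_true <- vapply(1:10, function(s) {
    p <- subject_profile(dominant_freq_hz = 8, coupling_strength = 1,
                         shared_source_gain = 0, seed = 900 + s)
    ep2 <- preprocess_recording(generate_subject_eeg(p, 30, fs),
                                target_rate_hz = fs, epoch_length_s = 2)
    wt <- wpli_threshold(ep2, 8, n_surrogates = 60, seed = s)
    wt$values["F3", "P3"] > 0
  }, logical(1))
  expect_gte(mean(kept_true), 0.95)

  ep <- noise_epochs(12, 4, 2 * fs, fs, labels = ch19[1:4])
  expect_error(wpli_threshold(ep, 8, n_surrogates = 0), "at least 20")
  # deterministic given the seed
  a <- wpli_threshold(ep, 8, n_surrogates = 30, seed = 7)
  b <- wpli_threshold(ep, 8, n_surrogates = 30, seed = 7)
  expect_identical(a$values, b$values)
})

test_that("coherence hits its analytic limits", {
  fs <- 250
  set.seed(55)
  # identical channels: coherence 1 at every bin
  x <- array(rnorm(30 * 1 * fs), c(30, 1, fs))
  arr <- array(0, c(30, 2, fs))
  arr[, 1, ] <- x[, 1, ]
  arr[, 2, ] <- x[, 1, ]
  ep <- make_epochs(arr, fs, c("F3", "F4"))
  coh <- coherence_matrix(ep, "full_band", pad_ratio = 1)
  expect_equal(coh$values[1, 2], 1, tolerance = 1e-9)

  # independent channels: mean coherence near the 1/n_epochs bias floor
  floors <- vapply(1:20, function(s) {
    epn <- noise_epochs(60, 2, fs, fs, seed = 600 + s, labels = c("F3", "F4"))
    coherence_matrix(epn, "full_band", pad_ratio = 1)$values[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(floors) - 1 / 60), 0.01)

  # y = x + independent equal-power noise at the signal frequency:
  # coherence = SNR/(1+SNR) = 0.5 there
  half <- vapply(1:10, function(s) {
    set.seed(650 + s)
    n_ep <- 60
    band <- function() t(vapply(seq_len(n_ep), function(e) {
      doceeg:::narrowband_oscillator(fs, fs, 10, bw_hz = 1)
    }, numeric(fs)))
    sig <- band()
    arr2 <- array(0, c(n_ep, 2, fs))
    arr2[, 1, ] <- sig
    arr2[, 2, ] <- sig + band()
    ep2 <- make_epochs(arr2, fs, c("F3", "F4"))
    coherence_matrix(ep2, "at_frequency", freq_hz = 10)$values[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(half) - 0.5), 0.1)

  expect_error(coherence_matrix(ep, "at_frequency"), "requires `freq_hz`")
})

test_that("mutual information hits its analytic limits", {
  set.seed(56)
  n <- 30000
  u <- runif(n)
  v <- runif(n)
  arr <- array(0, c(1, 2, n))
  arr[1, 1, ] <- u
  arr[1, 2, ] <- v
  ep <- make_epochs(arr, n, c("F3", "F4"))
  mi_ind <- mutual_information_matrix(ep)
  expect_lte(mi_ind$values[1, 2], 0.02)

  arr2 <- arr
  arr2[1, 2, ] <- u # y = x exactly
  mi_eq <- mutual_information_matrix(make_epochs(arr2, n, c("F3", "F4")))
  expect_equal(mi_eq$values[1, 2], log2(10), tolerance = 0.01)
  expect_equal(attr(mi_eq, "self_entropy_bits")[["F3"]], log2(10),
               tolerance = 0.01)

  # printed toy pair, 2 bins, vs exhaustive 2x2 joint table
  x <- c(1, 2, 8, 9, 3, 7)
  y <- c(2, 1, 9, 8, 7, 3)
  arr3 <- array(c(rep(x, 1), rep(y, 1)), c(1, 2, 6))
  arr3[1, 1, ] <- x
  arr3[1, 2, ] <- y
  ep3 <- make_epochs(arr3, 6, c("F3", "F4"))
  got <- tryCatch(mutual_information_matrix(ep3, n_bins = 2),
                  error = function(e) e)
  expect_s3_class(got, "error") # < 1000 samples is refused
  # the same computation through the oracle and through the kernel
  bins <- rbind(as.integer(x > 5), as.integer(y > 5))
  mi_kernel <- doceeg:::mi_accumulate(bins, 2L, c(TRUE, TRUE))
  expect_equal(mi_kernel[1, 2], oracle_mi_pair(x, y, n_bins = 2),
               tolerance = 1e-12)

  # constant channel: zero with a warning
  arr4 <- array(rnorm(2 * 2000), c(1, 2, 2000))
  arr4[1, 2, ] <- 5
  expect_warning(mi_c <- mutual_information_matrix(
    make_epochs(arr4, 2000, c("F3", "F4"))), "constant")
  expect_equal(mi_c$values[1, 2], 0)
})

test_that("Freedman-Diaconis bin count behaves sensibly", {
  set.seed(57)
  x <- rnorm(10000)
  nb <- fd_bin_count(x)
  expect_true(nb >= 10 && nb <= 60)
  expect_equal(fd_bin_count(rep(1, 100)), 2L)
})

test_that("ROI summaries follow the pair definitions", {
  ones <- connectivity_matrix(matrix(1, 19, 19), estimator = "MI")
  rs <- roi_summarize(ones)
  expect_true(all(unlist(rs) == 1))

  m <- matrix(0, 19, 19, dimnames = list(ch19, ch19))
  m["F3", "P3"] <- m["P3", "F3"] <- 1
  m["F7", "T5"] <- m["T5", "F7"] <- 1
  rs2 <- roi_summarize(connectivity_matrix(m, estimator = "MI"))
  expect_equal(rs2$left_frontoparietal, 2 / 6)
  expect_equal(rs2$right_frontoparietal, 0)
  expect_equal(rs2$frontal_inter, 0)
  expect_equal(rs2$global_mean, (2 / 6) / 5)

  bad_roi <- roi_pairs()[0, ]
  expect_error(roi_summarize(ones, roi = bad_roi))
})

test_that("estimators are invariant to channel scaling and permutation", {
  fs <- 250
  p <- subject_profile(dominant_freq_hz = 8, coupling_strength = 0.6,
                       shared_source_gain = 1, seed = 58)
  ep <- preprocess_recording(generate_subject_eeg(p, 20, fs),
                             target_rate_hz = fs)
  gains <- seq(0.5, 4, length.out = 19)
  ep_scaled <- ep
  for (ci in 1:19) ep_scaled$data[, ci, ] <- ep$data[, ci, ] * gains[ci]

  w1 <- wpli_matrix(morlet_tf(ep, 8))
  w2 <- wpli_matrix(morlet_tf(ep_scaled, 8))
  expect_equal(w1$values, w2$values, tolerance = 1e-9)

  c1 <- coherence_matrix(ep, "full_band", pad_ratio = 1)
  c2 <- coherence_matrix(ep_scaled, "full_band", pad_ratio = 1)
  expect_equal(c1$values, c2$values, tolerance = 1e-9)

  m1 <- mutual_information_matrix(ep)
  m2 <- mutual_information_matrix(ep_scaled)
  expect_equal(m1$values, m2$values, tolerance = 1e-9)

  # permuting channels permutes rows/columns consistently
  set.seed(59)
  perm <- sample(19)
  ep_perm <- ep
  ep_perm$data <- ep$data[, perm, , drop = FALSE]
  ep_perm$channel_labels <- ep$channel_labels[perm]
  mp <- mutual_information_matrix(ep_perm)
  expect_equal(mp$values, m1$values[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("wPLI discounts zero-lag mixing relative to lagged mixing", {
  fs <- 250
  for (cs in c(0.5, 1)) {
    w_lag <- numeric(5)
    w_zero <- numeric(5)
    for (s in 1:5) {
      p <- subject_profile(dominant_freq_hz = 8, coupling_strength = cs,
                           shared_source_gain = 0, seed = 800 + s)
      mk <- function(mode) {
        rec <- generate_subject_eeg(p, 20, fs, coupling_mode = mode)
        ep2 <- preprocess_recording(rec, target_rate_hz = fs,
                                    epoch_length_s = 2)
        w <- wpli_matrix(morlet_tf(ep2, 8))
        mean(w$values[default_coupled_pairs()])
      }
      w_lag[s] <- mk("lagged")
      w_zero[s] <- mk("zero_lag")
    }
    expect_lt(mean(w_zero), mean(w_lag))
  }
})

test_that("zero-lag common sources vanish after the Laplacian + wPLI chain", {
  fs <- 250
  set.seed(60)
  # common source into two non-adjacent channels (F3 and P4) on top of noise
  src_pair <- vapply(1:5, function(s) {
    set.seed(60 + s)
    n <- 40 * fs
    src <- as.numeric(arima.sim(list(ar = 0.95), n)) # smooth broadband
    arr <- array(rnorm(19 * n, sd = 1), c(1, 19, n))
    f3 <- match("F3", ch19)
    p4 <- match("P4", ch19)
    arr[1, f3, ] <- arr[1, f3, ] + src
    arr[1, p4, ] <- arr[1, p4, ] + src
    rec <- eeg_recording(matrix(arr[1, , ], nrow = 19,
                                dimnames = list(ch19, NULL)),
                         fs, subject_id = "zl")
    ep2 <- detrend_epochs(epoch_eeg(standardize(rec, target_rate_hz = fs), 2))
    lap <- laplacian_filter(ep2)
    wpli_matrix(morlet_tf(lap, 8))$values[f3, p4]
  }, numeric(1))
  expect_lt(mean(src_pair), 0.15)
})

test_that("coherence significance masks stay off the point estimates", {
  set.seed(61)
  ep <- noise_epochs(40, 19, 250, 250)
  coh <- coherence_matrix(ep, "full_band", pad_ratio = 1)
  sig <- coherence_significance(coh, n_epochs = 40)
  expect_true(is.logical(sig))
  expect_lt(mean(sig[upper.tri(sig)]), 0.2) # null data: mostly insignificant
})
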