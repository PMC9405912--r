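# Fixture builders and naive oracle implementations. Oracles use direct
# loops over the defining formulas and are kept independent of the package
# code paths they check.

ch19 <- channels_1020()

# A 19-channel recording where every channel carries the same deterministic
# construction rule (sinusoids and/or seeded noise).
make_recording <- function(n_s = 10, fs = 250, build = function(t, ch) 0 * t,
                           subject_id = "fix") {
  t <- seq(0, n_s - 1 / fs, by = 1 / fs)
  x <- t(vapply(seq_along(ch19), function(ci) build(t, ci), numeric(length(t))))
  eeg_recording(x, sampling_rate_hz = fs, channel_labels = ch19,
                subject_id = subject_id)
}

# Epoched data straight from an array, for toy fixtures with arbitrary
# channel counts.
make_epochs <- function(arr, fs, labels) {
  eeg_epochs(arr, epoch_length_s = dim(arr)[3] / fs, sampling_rate_hz = fs,
             channel_labels = labels)
}

# Toy multi-channel epochs of seeded Gaussian noise.
noise_epochs <- function(n_ep, n_ch, n_samp, fs, seed = 1,
                         labels = ch19[seq_len(n_ch)]) {
  set.seed(seed)
  make_epochs(array(rnorm(n_ep * n_ch * n_samp), c(n_ep, n_ch, n_samp)),
              fs, labels)
}

# --- oracles ---------------------------------------------------------------

# Morlet analytic signal by direct DFT sums (no FFT).
oracle_morlet <- function(x, fs, f0, n_cycles = 6) {
  n <- length(x)
  sigma_t <- n_cycles / (2 * pi * f0)
  sigma_f <- 1 / (2 * pi * sigma_t)
  freqs <- (seq_len(n) - 1) * fs / n
  H <- 2 * exp(-(freqs - f0)^2 / (2 * sigma_f^2))
  H[freqs > fs / 2] <- 0
  X <- vapply(seq_len(n), function(k) {
    sum(x * exp(-2i * pi * (k - 1) * (seq_len(n) - 1) / n))
  }, complex(1))
  vapply(seq_len(n), function(t) {
    sum(X * H * exp(2i * pi * (seq_len(n) - 1) * (t - 1) / n)) / n
  }, complex(1))
}

# wPLI from pooled complex samples, one pair at a time.
oracle_wpli_pair <- function(zx, zy) {
  im_s <- Im(zx * Conj(zy))
  den <- mean(abs(im_s))
  if (den == 0) return(0)
  abs(mean(im_s)) / den
}

# Magnitude-squared coherence from epoch-wise DFTs at given bins.
oracle_coherence_pair <- function(xe, ye, fs, bins_hz, pad_ratio) {
  n <- ncol(xe)
  nfft <- n * pad_ratio
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  dft <- function(v, f) sum(v * w * exp(-2i * pi * f / fs * (seq_len(n) - 1)))
  vals <- vapply(bins_hz, function(f) {
    Sxy <- 0 + 0i; Sxx <- 0; Syy <- 0
    for (e in seq_len(nrow(xe))) {
      X <- dft(xe[e, ], f)
      Y <- dft(ye[e, ], f)
      Sxy <- Sxy + X * Conj(Y)
      Sxx <- Sxx + Mod(X)^2
      Syy <- Syy + Mod(Y)^2
    }
    Mod(Sxy / nrow(xe))^2 / ((Sxx / nrow(xe)) * (Syy / nrow(xe)))
  }, numeric(1))
  mean(pmin(pmax(vals, 0), 1))
}

# Histogram MI in bits, naive counting.
oracle_mi_pair <- function(x, y, n_bins = 10) {
  bin_of <- function(v) {
    r <- range(v)
    b <- floor((v - r[1]) / diff(r) * n_bins)
    pmin(b, n_bins - 1) + 1
  }
  bx <- bin_of(x); by <- bin_of(y)
  n <- length(x)
  hx <- table(factor(bx, levels = 1:n_bins)) / n
  hy <- table(factor(by, levels = 1:n_bins)) / n
  hxy <- table(factor(bx, levels = 1:n_bins),
               factor(by, levels = 1:n_bins)) / n
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  ent(hx) + ent(hy) - ent(hxy)
}

# Permutation entropy by explicit pattern lookup.
oracle_peen <- function(series_list, m = 3, tau = 1) {
  pats <- list()
  for (x in series_list) {
    nw <- length(x) - (m - 1) * tau
    for (s in seq_len(nw)) {
      w <- x[s + (0:(m - 1)) * tau]
      pats[[length(pats) + 1]] <- paste(order(w), collapse = "")
    }
  }
  p <- table(unlist(pats))
  p <- p / sum(p)
  -sum(p * log(p)) / log(factorial(m))
}

# Surface Laplacian by explicit per-sample loops.
oracle_laplacian <- function(arr, labels, neighbors) {
  out <- arr
  for (e in seq_len(dim(arr)[1])) {
    for (ci in seq_along(labels)) {
      nb <- match(neighbors[[labels[ci]]], labels)
      out[e, ci, ] <- arr[e, ci, ] -
        colMeans(matrix(arr[e, nb, ], nrow = length(nb)))
    }
  }
  out
}

# ROI means by explicit pair loops.
oracle_roi <- function(values, labels, roi_tbl) {
  rois <- unique(roi_tbl$roi)
  v <- vapply(rois, function(r) {
    tb <- roi_tbl[roi_tbl$roi == r, ]
    mean(vapply(seq_len(nrow(tb)), function(k) {
      values[match(tb$ch1[k], labels), match(tb$ch2[k], labels)]
    }, numeric(1)))
  }, numeric(1))
  c(v, global = mean(v))
}

# The declared two-pass rejection rule, reimplemented naively.
oracle_reject <- function(arr, abs_thr, k) {
  n_ep <- dim(arr)[1]; n_ch <- dim(arr)[2]
  ptp <- vapply(seq_len(n_ep), function(e) {
    max(vapply(seq_len(n_ch), function(c) diff(range(arr[e, c, ])), numeric(1)))
  }, numeric(1))
  keep <- ptp <= abs_thr
  repeat {
    idx <- which(keep)
    if (length(idx) < 2) break
    ch_sd <- vapply(seq_len(n_ch), function(c) sd(as.vector(arr[idx, c, ])),
                    numeric(1))
    ch_sd[ch_sd < 1e-12] <- Inf
    score <- vapply(idx, function(e) {
      max(vapply(seq_len(n_ch), function(c) max(abs(arr[e, c, ])) / ch_sd[c],
                 numeric(1)))
    }, numeric(1))
    if (sd(score) < 1e-12 || !is.finite(sd(score))) break
    flag <- score > mean(score) + k * sd(score)
    if (!any(flag)) break
    keep[idx[flag]] <- FALSE
  }
  keep
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
oracle_mann_whitney_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  u_stat <- function(ia) {
    ra <- rank(pooled)[ia]
    sum(ra) - n * (n + 1) / 2
  }
  u_obs <- u_stat(seq_len(n))
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, u_stat)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Per-fold diagonal-LDA rule evaluated longhand.
oracle_diag_lda_predict <- function(Xtr, ytr, xte, positive) {
  classes <- sort(unique(ytr))
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, sd)
  Xs <- scale(Xtr, center = mu, scale = sdv)
  xs <- (xte - mu) / sdv
  pooled <- vapply(seq_len(ncol(Xs)), function(j) {
    ss <- 0
    for (cl in classes) {
      v <- Xs[ytr == cl, j]
      ss <- ss + sum((v - mean(v))^2)
    }
    ss / (nrow(Xs) - length(classes))
  }, numeric(1))
  delta <- vapply(classes, function(cl) {
    mk <- colMeans(Xs[ytr == cl, , drop = FALSE])
    -0.5 * sum((xs - mk)^2 / pooled) + log(mean(ytr == cl))
  }, numeric(1))
  classes[which.max(delta)]
}

# Split-plot ANOVA (balanced, no covariate) from explicit sums of squares.
oracle_split_plot_F <- function(Y, g) {
  k <- ncol(Y); n <- nrow(Y)
  groups <- unique(g)
  grand <- mean(Y)
  subj_mean <- rowMeans(Y)
  grp_mean <- tapply(subj_mean, g, mean)
  ss_group <- k * sum((grp_mean[g] - grand)^2)
  ss_subj_within <- k * sum((subj_mean - grp_mean[g])^2)
  df_group <- length(groups) - 1
  df_err <- n - length(groups)
  (ss_group / df_group) / (ss_subj_within / df_err)
}
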