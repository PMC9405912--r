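# Functional connectivity: surface Laplacian reference, Morlet
# time-frequency decomposition, weighted phase lag index with per-subject
# surrogate thresholding, epoch-averaged magnitude coherence, histogram
# mutual information, and ROI summaries.

#' 19x19 connectivity matrix container
#'
#' @param values Symmetric numeric matrix, diagonal 0.
#' @param estimator `"wPLI"`, `"PCoh"` or `"MI"`.
#' @param freq_context `"dominant_frequency"` or `"full_band"`.
#' @param freq_hz Frequency in Hz when `freq_context` is
#'   `"dominant_frequency"`.
#' @param thresholded Whether a surrogate threshold has been applied.
#' @param channel_labels Channel labels.
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(values,
                                estimator = c("wPLI", "PCoh", "MI"),
                                freq_context = c("full_band",
                                                 "dominant_frequency"),
                                freq_hz = NA_real_, thresholded = FALSE,
                                channel_labels = channels_1020()) {
  estimator <- match.arg(estimator)
  freq_context <- match.arg(freq_context)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-8) {
    stop("connectivity matrix must be symmetric", call. = FALSE)
  }
  diag(values) <- 0
  dimnames(values) <- list(channel_labels, channel_labels)
  structure(
    list(values = values, estimator = estimator,
         freq_context = freq_context, freq_hz = freq_hz,
         thresholded = thresholded, channel_labels = channel_labels),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf(
    "<connectivity_matrix> %s (%s%s)%s: %dx%d, mean %.4f, range [%.4f, %.4f]\n",
    x$estimator, x$freq_context,
    if (is.finite(x$freq_hz)) sprintf(" @ %g Hz", x$freq_hz) else "",
    if (x$thresholded) " thresholded" else "",
    nrow(x$values), ncol(x$values), mean(off), min(off), max(off)
  ))
  invisible(x)
}

#' Surface Laplacian re-reference
#'
#' Replaces each channel by itself minus the mean of its nearest
#' neighbours on the 10-20 layout, suppressing signal components common to
#' adjacent electrodes (volume-conducted sources).
#'
#' @param ep An [eeg_epochs()].
#' @param neighbors Named list of neighbour labels per channel; default
#'   [laplacian_neighbors()].
#' @return The filtered [eeg_epochs()].
#' @export
laplacian_filter <- function(ep, neighbors = laplacian_neighbors()) {
  stopifnot(inherits(ep, "eeg_epochs"))
  labs <- ep$channel_labels
  if (!all(labs %in% names(neighbors))) {
    stop("adjacency map must cover every channel", call. = FALSE)
  }
  nc <- n_channels(ep)
  L <- diag(nc)
  for (ci in seq_len(nc)) {
    nb <- match(neighbors[[labs[ci]]], labs)
    if (anyNA(nb)) stop("neighbour label missing from data", call. = FALSE)
    L[ci, nb] <- -1 / length(nb)
  }
  d <- ep$data
  flat <- matrix(aperm(d, c(2, 1, 3)), nrow = nc)
  flat <- L %*% flat
  out <- ep
  out$data <- aperm(array(flat, dim = c(nc, dim(d)[1], dim(d)[3])),
                    c(2, 1, 3))
  out
}

#' Morlet wavelet time-frequency decomposition at one frequency
#'
#' Complex analytic signal at `freq_hz` per epoch and channel, obtained by
#' frequency-domain multiplication with the spectrum of a complex Morlet
#' wavelet (Gaussian of width `freq_hz / n_cycles` centred on `freq_hz`,
#' positive frequencies only). Samples within half a wavelet support
#' (2.5 temporal SDs) of each epoch edge are flagged and excluded from all
#' downstream pooling.
#'
#' @param ep An [eeg_epochs()] (the phase-lag stage uses 2 s epochs).
#' @param freq_hz Analysis frequency in Hz (within 1-30).
#' @param n_cycles Wavelet width in cycles.
#' @return An `eeg_tf` object: complex array epochs x channels x samples
#'   with attribute `retained` (sample indices outside the edge zones).
#' @export
morlet_tf <- function(ep, freq_hz, n_cycles = 6) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (freq_hz < 1 || freq_hz > 30) {
    stop("`freq_hz` must lie in [1, 30]", call. = FALSE)
  }
  ns <- n_samples(ep)
  fs <- ep$sampling_rate_hz
  sigma_t <- n_cycles / (2 * pi * freq_hz)
  n_edge <- ceiling(2.5 * sigma_t * fs)
  if (2 * n_edge >= ns) stop("wavelet longer than epoch", call. = FALSE)
  sigma_f <- 1 / (2 * pi * sigma_t)
  freqs <- seq(0, fs, by = fs / ns)[seq_len(ns)]
  H <- 2 * exp(-(freqs - freq_hz)^2 / (2 * sigma_f^2))
  H[freqs > fs / 2] <- 0 # analytic: suppress negative frequencies
  flat <- t(matrix(ep$data, nrow = n_epochs(ep) * n_channels(ep), ncol = ns))
  Z <- stats::mvfft(stats::mvfft(flat) * H, inverse = TRUE) / ns
  tf <- array(t(Z), dim = dim(ep$data))
  structure(
    list(tf = tf, freq_hz = freq_hz, n_cycles = n_cycles,
         sampling_rate_hz = fs,
         retained = (n_edge + 1):(ns - n_edge),
         channel_labels = ep$channel_labels,
         subject_id = ep$subject_id),
    class = "eeg_tf"
  )
}

# Fast path equivalent to pool_tf_samples(morlet_tf(...)): the analytic
# signal is evaluated only at the decimated retained samples, through the
# wavelet's (numerically) non-zero spectral bins. Matches the full
# transform to ~1e-11 relative.
morlet_pooled <- function(ep, freq_hz, n_cycles = 6, step = NULL) {
  ns <- n_samples(ep)
  fs <- ep$sampling_rate_hz
  nep <- n_epochs(ep)
  nch <- n_channels(ep)
  sigma_t <- n_cycles / (2 * pi * freq_hz)
  n_edge <- ceiling(2.5 * sigma_t * fs)
  if (2 * n_edge >= ns) stop("wavelet longer than epoch", call. = FALSE)
  retained <- (n_edge + 1):(ns - n_edge)
  step <- step %||% max(1L, round(fs / (4 * freq_hz)))
  t_sel <- retained[seq(1, length(retained), by = step)]

  sigma_f <- 1 / (2 * pi * sigma_t)
  freqs <- seq(0, fs, by = fs / ns)[seq_len(ns)]
  H <- 2 * exp(-(freqs - freq_hz)^2 / (2 * sigma_f^2))
  H[freqs > fs / 2] <- 0
  bsel <- which(H > 1e-14)

  # forward FFTs, two real columns packed per complex transform
  flat <- t(matrix(ep$data, nrow = nep * nch, ncol = ns)) # ns x (ep*ch)
  k <- ncol(flat)
  Fsel <- matrix(0 + 0i, length(bsel), k)
  rev_idx <- c(1L, ns:2L)[bsel]
  for (j in seq(1, k, by = 2)) {
    z <- if (j < k) flat[, j] + 1i * flat[, j + 1] else flat[, j]
    Fz <- stats::fft(z)
    Fc <- Conj(Fz[rev_idx])
    Fsel[, j] <- (Fz[bsel] + Fc) / 2
    if (j < k) Fsel[, j + 1] <- (Fz[bsel] - Fc) / (2i)
  }
  # inverse DFT at the selected time points only
  E <- exp(2i * pi * outer(t_sel - 1, bsel - 1) / ns) / ns
  Zd <- E %*% (Fsel * H[bsel]) # n_sel x (ep*ch)
  # column c of Zd corresponds to (epoch e, channel ci) with e fastest;
  # rearrange to channels x (epochs * n_sel), epochs consecutive
  Za <- array(Zd, dim = c(length(t_sel), nep, nch))
  z <- matrix(aperm(Za, c(3, 1, 2)), nrow = nch)
  list(z = z, n_per_epoch = length(t_sel), n_epochs = nep)
}

# Pool the retained analytic samples to channels x N, decimated to about
# four samples per cycle of the analysis frequency (the analytic signal is
# bandlimited to the wavelet bandwidth, so denser sampling is redundant).
pool_tf_samples <- function(tf, step = NULL) {
  step <- step %||% max(1L, round(tf$sampling_rate_hz / (4 * tf$freq_hz)))
  idx <- tf$retained[seq(1, length(tf$retained), by = step)]
  d <- tf$tf[, , idx, drop = FALSE]
  n_ep <- dim(d)[1]
  z <- matrix(aperm(d, c(2, 3, 1)), nrow = dim(d)[2])
  list(z = z, n_per_epoch = length(idx), n_epochs = n_ep)
}

#' Weighted phase lag index matrix
#'
#' For each channel pair, with the cross-spectrum `S = X * Conj(Y)` pooled
#' over epochs and retained time samples,
#' `wPLI = |mean(Im S)| / mean(|Im S|)` (0 when the denominator vanishes,
#' e.g. for strictly zero-lag coupling). Values lie in `[0, 1]`; the
#' estimator discounts zero-lag (volume-conducted) interactions.
#'
#' @param tf An `eeg_tf` from [morlet_tf()] with at least 10 epochs.
#' @param step Decimation step over retained samples; default about four
#'   samples per cycle of the analysis frequency.
#' @return A `connectivity_matrix` (estimator `"wPLI"`).
#' @export
wpli_matrix <- function(tf, step = NULL) {
  stopifnot(inherits(tf, "eeg_tf"))
  if (dim(tf$tf)[1] < 10) stop("wPLI needs at least 10 epochs", call. = FALSE)
  if (dim(tf$tf)[2] < 2) stop("wPLI needs at least 2 channels", call. = FALSE)
  pool <- pool_tf_samples(tf, step)
  wpli_from_pooled(pool$z, tf)
}

wpli_from_pooled <- function(z, tf) {
  acc <- wpli_accumulate(Re(z), Im(z))
  den <- acc$sum_abs
  num <- abs(acc$sum_im)
  vals <- matrix(0, nrow(den), ncol(den))
  nz <- den > 1e-300
  vals[nz] <- num[nz] / den[nz]
  connectivity_matrix(vals, estimator = "wPLI",
                      freq_context = "dominant_frequency",
                      freq_hz = tf$freq_hz,
                      channel_labels = tf$channel_labels)
}

#' Surrogate-thresholded wPLI
#'
#' Builds a per-subject null by recomputing the wPLI on surrogates in
#' which each channel's analytic signal is independently circularly
#' time-shifted within every epoch (spectra preserved, cross-channel phase
#' relations destroyed). Pair values below the `1 - alpha` quantile of
#' their own surrogate distribution are set to 0.
#'
#' @param ep2s An [eeg_epochs()] (2 s epochs recommended).
#' @param freq_hz Analysis frequency (the subject's dominant frequency).
#' @param n_surrogates Number of surrogates (>= 20).
#' @param alpha Upper tail probability for the threshold.
#' @param seed Integer seed; the result is deterministic given it.
#' @param n_cycles Morlet width in cycles.
#' @return A thresholded `connectivity_matrix` with attributes
#'   `threshold` (19x19 matrix of pair thresholds) and `raw` (unthresholded
#'   values).
#' @export
wpli_threshold <- function(ep2s, freq_hz, n_surrogates = 200, alpha = 0.05,
                           seed = 1L, n_cycles = 6) {
  if (n_surrogates < 20) {
    stop("`n_surrogates` must be at least 20", call. = FALSE)
  }
  if (n_epochs(ep2s) < 10) stop("wPLI needs at least 10 epochs", call. = FALSE)
  pool <- morlet_pooled(ep2s, freq_hz, n_cycles = n_cycles)
  tf_meta <- list(freq_hz = freq_hz, channel_labels = ep2s$channel_labels)
  base <- wpli_from_pooled(pool$z, tf_meta)

  local_seed(seed)
  nc <- nrow(pool$z)
  npe <- pool$n_per_epoch
  nep <- pool$n_epochs
  shifts <- matrix(sample.int(npe, nc * nep * n_surrogates,
                              replace = TRUE) - 1L,
                   nrow = nc)
  sur <- wpli_surrogates(Re(pool$z), Im(pool$z), npe, nep, shifts,
                         n_surrogates)
  thr <- apply(sur, c(1, 2), stats::quantile, probs = 1 - alpha)
  vals <- base$values
  vals[vals < thr] <- 0
  out <- connectivity_matrix(vals, estimator = "wPLI",
                             freq_context = "dominant_frequency",
                             freq_hz = freq_hz, thresholded = TRUE,
                             channel_labels = ep2s$channel_labels)
  attr(out, "threshold") <- thr
  attr(out, "raw") <- base$values
  out
}

#' Epoch-averaged magnitude coherence matrix
#'
#' Magnitude-squared coherence per channel pair from epoch-averaged cross-
#' and auto-spectra, `|<Sxy>|^2 / (<Sxx> <Syy>)`, computed with Hann
#' tapering and zero padding by `pad_ratio` (frequency resolution
#' `fs / (pad_ratio * n_samples)`). `full_band` averages the coherence
#' over the analysis band; `at_frequency` reads the bin nearest `freq_hz`.
#'
#' @param ep An [eeg_epochs()] (Laplacian-referenced for the partial
#'   coherence reading).
#' @param mode `"full_band"` or `"at_frequency"`.
#' @param freq_hz Required in `at_frequency` mode.
#' @param pad_ratio Zero-padding factor.
#' @param band Analysis band for `full_band`, default `c(1, 30)`.
#' @return A `connectivity_matrix` (estimator `"PCoh"`).
#' @export
coherence_matrix <- function(ep, mode = c("full_band", "at_frequency"),
                             freq_hz = NULL, pad_ratio = 8, band = c(1, 30)) {
  stopifnot(inherits(ep, "eeg_epochs"))
  mode <- match.arg(mode)
  if (mode == "at_frequency" && is.null(freq_hz)) {
    stop("`at_frequency` mode requires `freq_hz`", call. = FALSE)
  }
  ns <- n_samples(ep)
  fs <- ep$sampling_rate_hz
  nc <- n_channels(ep)
  nep <- n_epochs(ep)
  nfft <- ns * pad_ratio
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  sel <- if (mode == "full_band") {
    which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
  } else {
    which.min(abs(freqs - freq_hz))
  }
  nb <- length(sel)
  # Hann-tapered DFT evaluated only at the selected padded-grid bins
  w <- hann_window(ns)
  t_idx <- seq_len(ns) - 1
  E <- exp(-2i * pi * outer(t_idx, (sel - 1) / nfft)) * w # ns x bins
  flat <- matrix(ep$data, nrow = nep * nc, ncol = ns) # (ep*ch) x ns
  X <- flat %*% Re(E) + (0 + 1i) * (flat %*% Im(E)) # (ep*ch) x bins
  # per-bin epoch-averaged cross-spectral matrices
  num <- array(0, dim = c(nc, nc, nb)) # |<Sxy>|^2
  den <- array(0, dim = c(nc, nc, nb)) # <Sxx><Syy>
  for (b in seq_len(nb)) {
    Xb <- matrix(X[, b], nrow = nep, ncol = nc)
    S <- crossprod(Conj(Xb), Xb) / nep
    auto <- Re(diag(S))
    num[, , b] <- Mod(S)^2
    den[, , b] <- outer(auto, auto)
  }
  coh <- num / pmax(den, 1e-300)
  coh <- pmin(pmax(coh, 0), 1)
  vals <- matrix(rowMeans(matrix(coh, nrow = nc * nc, ncol = nb)), nc, nc)
  vals <- (vals + t(vals)) / 2
  connectivity_matrix(vals, estimator = "PCoh",
                      freq_context = if (mode == "full_band") "full_band"
                      else "dominant_frequency",
                      freq_hz = if (mode == "full_band") NA_real_ else
                        freqs[sel][1],
                      channel_labels = ep$channel_labels)
}

#' Histogram mutual information matrix
#'
#' Amplitudes of each channel (kept epochs concatenated) are binned into
#' `n_bins` equal-width bins spanning the channel's observed range;
#' `MI = H(X) + H(Y) - H(X, Y)` in bits. A constant channel has undefined
#' bins; its pairs are reported as 0 with a warning.
#'
#' @param ep An [eeg_epochs()] with at least 1000 concatenated samples per
#'   channel.
#' @param n_bins Number of histogram bins (default 10; see
#'   [fd_bin_count()] for a Freedman-Diaconis-derived alternative).
#' @return A `connectivity_matrix` (estimator `"MI"`) with attribute
#'   `self_entropy_bits` (per-channel H(X)).
#' @export
mutual_information_matrix <- function(ep, n_bins = 10) {
  stopifnot(inherits(ep, "eeg_epochs"))
  x <- concat_epochs(ep)
  n <- ncol(x)
  if (n < 1000) {
    stop("mutual information needs at least 1000 samples per channel",
         call. = FALSE)
  }
  nc <- nrow(x)
  bin_idx <- matrix(0L, nc, n)
  ok <- rep(TRUE, nc)
  for (ci in seq_len(nc)) {
    r <- range(x[ci, ])
    if (diff(r) < 1e-12) {
      ok[ci] <- FALSE
      next
    }
    b <- floor((x[ci, ] - r[1]) / diff(r) * n_bins)
    bin_idx[ci, ] <- pmin(as.integer(b), n_bins - 1L)
  }
  if (!all(ok)) {
    warning("constant channel(s): ",
            paste(rownames(x)[!ok], collapse = ", "),
            "; their MI set to 0")
  }
  vals <- mi_accumulate(bin_idx, as.integer(n_bins), ok)
  H <- stats::setNames(diag(vals), ep$channel_labels)
  out <- connectivity_matrix(vals, estimator = "MI",
                             channel_labels = ep$channel_labels)
  attr(out, "self_entropy_bits") <- H
  out
}

#' Freedman-Diaconis bin count
#'
#' Bin count from the Freedman-Diaconis rule (bin width `2 IQR / n^(1/3)`)
#' applied to a channel's pooled amplitudes; offered as an alternative to
#' the fixed default of 10 bins.
#'
#' @param x Numeric vector of amplitudes.
#' @return Integer bin count (at least 2).
#' @export
fd_bin_count <- function(x) {
  h <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (h <= 0) return(2L)
  max(2L, as.integer(ceiling(diff(range(x)) / h)))
}

#' Summarise a connectivity matrix into ROIs
#'
#' ROI value = mean of the matrix over the ROI's electrode pairs;
#' `global_mean` = mean of the five ROI values.
#'
#' @param m A `connectivity_matrix`.
#' @param roi ROI pair table as from [roi_pairs()].
#' @return One-row tibble: the five ROI means and `global_mean`.
#' @export
roi_summarize <- function(m, roi = roi_pairs()) {
  stopifnot(inherits(m, "connectivity_matrix"))
  labs <- m$channel_labels
  vals <- vapply(split(roi, roi$roi), function(tb) {
    if (nrow(tb) == 0) stop("ROI with empty pair set", call. = FALSE)
    i <- match(tb$ch1, labs)
    j <- match(tb$ch2, labs)
    if (anyNA(i) || anyNA(j)) stop("ROI electrode missing", call. = FALSE)
    mean(m$values[cbind(i, j)])
  }, numeric(1))
  out <- tibble::as_tibble(as.list(vals))[, roi_names()]
  out$global_mean <- mean(unlist(vals))
  out
}

#' Benjamini-Hochberg significance mask for a coherence matrix
#'
#' Optional multiple-comparison handling over the 171 electrode pairs:
#' p-values from the standard F-approximation for magnitude-squared
#' coherence with `n_epochs` independent segments are FDR-adjusted; the
#' returned logical matrix marks significant pairs. Point estimates are
#' never altered.
#'
#' @param m A `"PCoh"` `connectivity_matrix`.
#' @param n_epochs Number of averaged epochs.
#' @param alpha FDR level.
#' @return Logical matrix of significant pairs.
#' @export
coherence_significance <- function(m, n_epochs, alpha = 0.05) {
  stopifnot(inherits(m, "connectivity_matrix"), m$estimator == "PCoh")
  ut <- upper.tri(m$values)
  coh <- m$values[ut]
  # under H0, (n-1) * C / (1 - C) ~ F(2, 2(n-1))
  p <- stats::pf((n_epochs - 1) * coh / pmax(1 - coh, 1e-12),
                 2, 2 * (n_epochs - 1), lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  sig <- matrix(FALSE, nrow(m$values), ncol(m$values))
  sig[ut] <- padj < alpha
  sig | t(sig)
}

#' Write a connectivity matrix as labelled CSV
#'
#' @param m A `connectivity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connectivity_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m$values), path, row.names = TRUE)
  invisible(path)
}

#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(as.table(object$values)))
  names(df) <- c("ch1", "ch2", "value")
  df$ch1 <- factor(df$ch1, levels = object$channel_labels)
  df$ch2 <- factor(df$ch2, levels = rev(object$channel_labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ch1, y = .data$ch2,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = object$estimator) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s connectivity", object$estimator)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}
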