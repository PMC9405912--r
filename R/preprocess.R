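# Preprocessing: resample + zero-phase bandpass, fixed-length epoching,
# two-pass artefact rejection with an auditable log, linear detrending.

#' Resample and bandpass a recording
#'
#' Brings a recording to the analysis rate and band: FFT-based
#' band-limited resampling (the spectrum is truncated at the new Nyquist,
#' which is also an ideal anti-alias filter) followed by zero-phase
#' frequency-domain bandpass filtering with exact band edges (response 1
#' inside the band, 0 outside): a spectral projection, so filtering twice
#' equals filtering once. Circular-transform ringing at the recording ends
#' is absorbed by the subsequent epoching, rejection and detrending stages.
#'
#' @param rec An [eeg_recording()].
#' @param target_rate_hz Output sampling rate (must not exceed the input
#'   rate).
#' @param band Length-2 passband in Hz, default `c(1, 30)`.
#' @return An [eeg_recording()] at `target_rate_hz`.
#' @export
standardize <- function(rec, target_rate_hz = 500, band = c(1, 30)) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (band[1] >= band[2]) stop("band edges inverted", call. = FALSE)
  if (band[2] >= target_rate_hz / 2) {
    stop("band upper edge must be below the target Nyquist frequency",
         call. = FALSE)
  }
  if (target_rate_hz > rec$sampling_rate_hz) {
    stop("`target_rate_hz` must not exceed the original rate", call. = FALSE)
  }
  x <- rec$data
  fs <- rec$sampling_rate_hz
  if (abs(target_rate_hz - fs) > 1e-9) {
    m <- round(ncol(x) * target_rate_hz / fs)
    x <- t(apply(x, 1, fft_resample, m = m))
    fs <- target_rate_hz
  }
  x <- fft_bandpass_rows(x, fs = fs, band = band)
  eeg_recording(x, sampling_rate_hz = fs, channel_labels = rec$channel_labels,
                subject_id = rec$subject_id)
}

# Exact band-limited resampling: truncate/extend the spectrum to m bins.
fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(length.out = m)
  keep <- min(n, m)
  h <- floor(keep / 2)
  Y[1:(h + 1)] <- X[1:(h + 1)]
  if (h > 0) Y[(m - h + 1):m] <- X[(n - h + 1):n]
  if (keep %% 2 == 0) {
    # split the shared Nyquist bin to keep the result real
    Y[h + 1] <- Y[h + 1] / 2
    Y[m - h + 1] <- Conj(Y[h + 1])
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' @noRd
fft_bandpass <- function(x, fs, band, trans = c(0, 0)) {
  drop(fft_bandpass_rows(matrix(x, nrow = 1), fs, band, trans))
}

# Zero-phase frequency-domain bandpass on the rows of a matrix: the DFT is
# multiplied by a response that is exactly 1 inside the band and 0 outside
# (raised-cosine transitions of the given widths are available). With the
# default hard edges the operation is an orthogonal projection, so
# filtering twice equals filtering once; start/end ringing from the
# circular transform is handled by the later epoching stages. The response
# is real and even, so two real channels share one complex FFT
# (x1 + i*x2 filters to y1 + i*y2).
fft_bandpass_rows <- function(x, fs, band, trans = c(0, 0)) {
  n <- ncol(x)
  f <- seq(0, fs, by = fs / n)[seq_len(n)]
  f <- pmin(f, fs - f) # two-sided frequency axis
  lo <- if (trans[1] > 0) {
    raised_cosine(f, band[1] - trans[1], band[1])
  } else {
    as.numeric(f >= band[1])
  }
  hi <- if (trans[2] > 0) {
    1 - raised_cosine(f, band[2], band[2] + trans[2])
  } else {
    as.numeric(f <= band[2])
  }
  H <- lo * hi
  k <- nrow(x)
  out <- matrix(0, k, n)
  for (j in seq(1, k, by = 2)) {
    z <- if (j < k) x[j, ] + 1i * x[j + 1, ] else x[j, ]
    y <- stats::fft(stats::fft(z) * H, inverse = TRUE) / n
    out[j, ] <- Re(y)
    if (j < k) out[j + 1, ] <- Im(y)
  }
  dimnames(out) <- dimnames(x)
  out
}

# 0 below f0, 1 above f1, half-cosine ramp in between.
raised_cosine <- function(f, f0, f1) {
  r <- (f - f0) / (f1 - f0)
  r <- pmin(pmax(r, 0), 1)
  0.5 - 0.5 * cos(pi * r)
}

#' Cut a recording into fixed-length epochs
#'
#' Non-overlapping epochs; a trailing partial segment is discarded.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_length_s Epoch length in seconds (default 1 s; the phase-lag
#'   stage re-epochs at 2 s).
#' @return An [eeg_epochs()] with all epochs kept.
#' @export
epoch_eeg <- function(rec, epoch_length_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_samp <- round(epoch_length_s * rec$sampling_rate_hz)
  n_ep <- floor(ncol(rec$data) / n_samp)
  if (n_ep < 1) stop("epoch longer than recording", call. = FALSE)
  d <- rec$data[, seq_len(n_ep * n_samp), drop = FALSE]
  dim(d) <- c(nrow(d), n_samp, n_ep)
  eeg_epochs(aperm(d, c(3, 1, 2)), epoch_length_s = epoch_length_s,
             sampling_rate_hz = rec$sampling_rate_hz,
             channel_labels = rec$channel_labels,
             subject_id = rec$subject_id)
}

#' Two-pass automatic artefact rejection
#'
#' Pass 1 drops epochs whose peak-to-peak amplitude on any channel exceeds
#' `abs_threshold_uv`. Pass 2 targets statistically extreme epochs: each
#' epoch is scored by its largest absolute sample after per-channel
#' scaling by the channel SD over the currently kept epochs, and epochs
#' whose score exceeds `mean + sd_multiplier * SD` of the score
#' distribution are dropped, iterating until no epoch exceeds the bound
#' (at most eight iterations). Zero-variance score distributions (e.g.
#' identical epochs) reject nothing. Kept epochs are returned unchanged in
#' value; `kept_mask` and `rejection_log` exactly partition the original
#' epoch indices.
#'
#' @param ep An [eeg_epochs()] with at least 2 epochs.
#' @param abs_threshold_uv Absolute peak-to-peak threshold in µV (pass 1).
#' @param sd_multiplier SD multiplier for the extreme-amplitude pass.
#' @return An [eeg_epochs()] containing the kept epochs.
#' @export
reject_artifacts <- function(ep, abs_threshold_uv = 500, sd_multiplier = 3) {
  stopifnot(inherits(ep, "eeg_epochs"))
  n_ep <- n_epochs(ep)
  if (n_ep < 2) stop("artefact rejection needs at least 2 epochs", call. = FALSE)
  orig_idx <- which(ep$kept_mask)

  nch <- n_channels(ep)
  nsm <- n_samples(ep)
  # (epochs*channels) x samples view; row r <-> (epoch, channel)
  flat <- matrix(ep$data, nrow = n_ep * nch, ncol = nsm)
  rr <- row_range_stats(flat)
  row_max <- matrix(rr$max, n_ep, nch)
  row_min <- matrix(rr$min, n_ep, nch)
  row_abs <- matrix(rr$absmax, n_ep, nch) # epoch x channel max |x|

  # pass 1: absolute peak-to-peak amplitude
  ptp <- apply(row_max - row_min, 1, max)
  bad1 <- ptp > abs_threshold_uv
  log1 <- tibble::tibble(epoch = orig_idx[bad1],
                         reason = "amplitude above absolute threshold")
  keep <- !bad1
  if (!any(keep)) stop("empty after rejection", call. = FALSE)

  # per-epoch/channel sums for fast SD over any subset of epochs
  s1 <- matrix(rowSums(flat), n_ep, nch)
  s2 <- matrix(rowSums(flat^2), n_ep, nch)

  # pass 2: iterative extreme-value rejection on normalized epoch maxima
  bad2 <- rep(FALSE, n_ep)
  for (iter in 1:8) {
    idx <- which(keep & !bad2)
    if (length(idx) < 2) break
    n_tot <- length(idx) * nsm
    mu <- colSums(s1[idx, , drop = FALSE]) / n_tot
    ch_var <- colSums(s2[idx, , drop = FALSE]) / n_tot - mu^2
    ch_sd <- sqrt(pmax(ch_var, 0) * n_tot / (n_tot - 1))
    ch_sd[ch_sd < 1e-12] <- Inf # flat channels cannot flag epochs
    score <- apply(row_abs[idx, , drop = FALSE] %*% diag(1 / ch_sd, nch),
                   1, max)
    sd_s <- stats::sd(score)
    if (!is.finite(sd_s) || sd_s < 1e-12) break
    thr <- mean(score) + sd_multiplier * sd_s
    flag <- score > thr
    if (!any(flag)) break
    bad2[idx[flag]] <- TRUE
  }
  log2 <- tibble::tibble(epoch = orig_idx[bad2],
                         reason = sprintf("samples beyond %g SD", sd_multiplier))
  keep <- keep & !bad2
  if (!any(keep)) stop("empty after rejection", call. = FALSE)

  new_mask <- ep$kept_mask
  new_mask[orig_idx[!keep]] <- FALSE
  eeg_epochs(
    ep$data[keep, , , drop = FALSE],
    epoch_length_s = ep$epoch_length_s,
    sampling_rate_hz = ep$sampling_rate_hz,
    channel_labels = ep$channel_labels,
    kept_mask = new_mask,
    rejection_log = dplyr::arrange(
      dplyr::bind_rows(ep$rejection_log, log1, log2), .data$epoch
    ),
    subject_id = ep$subject_id
  )
}

#' Remove linear trends from every epoch
#'
#' Per epoch and channel, the least-squares straight line is subtracted,
#' leaving each trace with (numerically) zero mean and zero linear trend.
#'
#' @param ep An [eeg_epochs()].
#' @return The detrended [eeg_epochs()].
#' @export
detrend_epochs <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  ns <- n_samples(ep)
  t_c <- seq_len(ns) - (ns + 1) / 2 # centered regressor
  sxx <- sum(t_c^2)
  d <- ep$data
  flat <- matrix(d, nrow = n_epochs(ep) * n_channels(ep), ncol = ns)
  slope <- (flat %*% t_c) / sxx
  fitted <- rowMeans(flat) + slope %*% t_c
  d <- array(flat - fitted, dim = dim(d))
  out <- ep
  out$data <- d
  out
}

#' Full preprocessing chain for one recording
#'
#' [standardize()] then [epoch_eeg()], [reject_artifacts()] and
#' [detrend_epochs()].
#'
#' @param rec An [eeg_recording()].
#' @param target_rate_hz,band Passed to [standardize()].
#' @param epoch_length_s Passed to [epoch_eeg()].
#' @param abs_threshold_uv,sd_multiplier Passed to [reject_artifacts()].
#' @return A clean [eeg_epochs()].
#' @export
preprocess_recording <- function(rec, target_rate_hz = 500, band = c(1, 30),
                                 epoch_length_s = 1, abs_threshold_uv = 500,
                                 sd_multiplier = 3) {
  rec |>
    standardize(target_rate_hz = target_rate_hz, band = band) |>
    epoch_eeg(epoch_length_s = epoch_length_s) |>
    reject_artifacts(abs_threshold_uv = abs_threshold_uv,
                     sd_multiplier = sd_multiplier) |>
    detrend_epochs()
}

#' Rejection report as JSON
#'
#' Serialises the rejection log of an epoched object for audit.
#'
#' @param ep An [eeg_epochs()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_rejection_report <- function(ep, path) {
  jsonlite::write_json(
    list(
      subject_id = ep$subject_id,
      n_epochs_original = length(ep$kept_mask),
      n_epochs_kept = sum(ep$kept_mask),
      rejections = ep$rejection_log
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
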