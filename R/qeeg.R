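# Quantitative EEG measures: z-scored band power, dominant frequency,
# permutation entropy, mean amplitude.

#' Average power spectrum of epoched EEG
#'
#' Modified (Hann-tapered) periodograms per epoch and channel, averaged
#' over epochs and then electrodes, restricted to the analysis band. With
#' this scaling the band-integrated power (sum of power times bin width)
#' approximates the in-band signal variance (Parseval). `z_power` is the
#' power z-scored across the retained frequency bins, which makes the
#' spectral shape (and thus the dominant frequency) scale-free.
#'
#' @param ep An [eeg_epochs()] with at least one kept epoch.
#' @param band Retained frequency range in Hz, default `c(1, 30)`.
#' @return An `eeg_spectrum`: tibble with columns `freq_hz`, `power`
#'   (µV²/Hz), `z_power`.
#' @export
compute_spectrum <- function(ep, band = c(1, 30)) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (n_epochs(ep) < 1) stop("no kept epochs", call. = FALSE)
  ns <- n_samples(ep)
  fs <- ep$sampling_rate_hz
  w <- hann_window(ns)
  flat <- t(matrix(ep$data, nrow = n_epochs(ep) * n_channels(ep), ncol = ns))
  X <- stats::mvfft(flat * w)
  pwr <- rowMeans(Mod(X)^2) / (fs * sum(w^2))
  n_keep <- floor(ns / 2) + 1
  pwr <- pwr[seq_len(n_keep)]
  pwr[2:(n_keep - 1)] <- 2 * pwr[2:(n_keep - 1)] # one-sided
  freqs <- (seq_len(n_keep) - 1) * fs / ns
  sel <- freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9
  out <- tibble::tibble(
    freq_hz = freqs[sel],
    power = pwr[sel],
    z_power = as.numeric(scale(pwr[sel]))
  )
  class(out) <- c("eeg_spectrum", class(out))
  attr(out, "sampling_rate_hz") <- fs
  attr(out, "band") <- band
  out
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' Dominant frequency of a spectrum
#'
#' Frequency of the global maximum of the z-scored power over the retained
#' band; ties break towards the lower frequency.
#'
#' @param spectrum An `eeg_spectrum` from [compute_spectrum()].
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(spectrum) {
  stopifnot(inherits(spectrum, "eeg_spectrum"))
  spectrum$freq_hz[which.max(spectrum$z_power)]
}

#' Mean z-scored power per frequency band
#'
#' Band means of `z_power` over delta (1-3 Hz), theta (4-7 Hz), alpha
#' (8-13 Hz) and beta (14-30 Hz); a bin falling on a shared band edge is
#' assigned to the lower band.
#'
#' @param spectrum An `eeg_spectrum`.
#' @return One-row tibble `zpsd_delta`, `zpsd_theta`, `zpsd_alpha`,
#'   `zpsd_beta`.
#' @export
band_zpower <- function(spectrum) {
  f <- spectrum$freq_hz
  band <- dplyr::case_when(
    f <= 3.5 ~ "zpsd_delta",
    f <= 7.5 ~ "zpsd_theta",
    f <= 13.5 ~ "zpsd_alpha",
    TRUE ~ "zpsd_beta"
  )
  out <- tapply(spectrum$z_power, band, mean)
  tibble::as_tibble(as.list(out))[, c("zpsd_delta", "zpsd_theta",
                                      "zpsd_alpha", "zpsd_beta")]
}

#' Permutation entropy per electrode
#'
#' Shannon entropy of the distribution of ordinal patterns of length `m`
#' (embedding delay `tau`), pooled over all kept epochs of each channel
#' and normalised by `log(m!)` so the value lies in `[0, 1]`. Ties between
#' samples are broken by order of occurrence.
#'
#' @param ep An [eeg_epochs()].
#' @param m Pattern order (>= 2).
#' @param tau Embedding delay in samples.
#' @return List with `per_electrode` (named numeric) and `mean`.
#' @export
permutation_entropy <- function(ep, m = 3, tau = 1) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (m < 2) stop("pattern order `m` must be at least 2", call. = FALSE)
  ns <- n_samples(ep)
  if (ns <= (m - 1) * tau) {
    stop("epoch length must exceed (m - 1) * tau samples", call. = FALSE)
  }
  nw <- ns - (m - 1) * tau
  n_pat <- factorial(m)
  fact <- factorial((m - 1):0)
  per <- vapply(seq_len(n_channels(ep)), function(ci) {
    x <- ep$data[, ci, , drop = FALSE] # epochs x 1 x samples
    cols <- lapply(seq_len(m), function(j) {
      as.numeric(x[, 1, ((j - 1) * tau + 1):((j - 1) * tau + nw)])
    })
    lehmer <- numeric(length(cols[[1]]))
    for (j in seq_len(m - 1)) {
      cj <- 0
      for (k in (j + 1):m) cj <- cj + (cols[[k]] < cols[[j]])
      lehmer <- lehmer + cj * fact[j]
    }
    p <- tabulate(lehmer + 1, n_pat)
    p <- p / sum(p)
    p <- p[p > 0]
    -sum(p * log(p)) / log(n_pat)
  }, numeric(1))
  names(per) <- ep$channel_labels
  list(per_electrode = per, mean = mean(per))
}

#' Mean absolute amplitude
#'
#' Mean absolute value of the (detrended) signal over epochs, channels and
#' samples, in µV. The absolute value keeps the measure informative for a
#' zero-mean signal.
#'
#' @param ep An [eeg_epochs()].
#' @return Scalar µV.
#' @export
mean_amplitude <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  mean(abs(ep$data))
}

#' All qEEG features of one subject
#'
#' @param ep A clean (rejected, detrended) [eeg_epochs()].
#' @param band Spectral band, default `c(1, 30)`.
#' @param peen_m,peen_tau Permutation-entropy order and delay.
#' @return One-row tibble: `dominant_freq_hz`, the four `zpsd_*` bands,
#'   `peen_mean`, `amp_mean_uv`.
#' @export
qeeg_features <- function(ep, band = c(1, 30), peen_m = 3, peen_tau = 1) {
  spec <- compute_spectrum(ep, band = band)
  pe <- permutation_entropy(ep, m = peen_m, tau = peen_tau)
  dplyr::bind_cols(
    tibble::tibble(dominant_freq_hz = dominant_frequency(spec)),
    band_zpower(spec),
    tibble::tibble(peen_mean = pe$mean, amp_mean_uv = mean_amplitude(ep))
  )
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.eeg_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_hz, y = .data$z_power)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = object[which.max(object$z_power), ],
      colour = "red", size = 2
    ) +
    ggplot2::labs(x = "Frequency (Hz)", y = "z-scored PSD",
                  title = "Average power spectrum") +
    ggplot2::theme_minimal()
}
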