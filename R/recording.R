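# Signal containers: continuous recordings and epoched data.

#' Continuous multichannel EEG recording
#'
#' Light S3 container for a continuous recording: a channels x samples
#' matrix in microvolts plus sampling rate and 10-20 channel labels.
#'
#' @param data Numeric matrix, channels x samples (µV).
#' @param sampling_rate_hz Sampling rate in Hz (positive).
#' @param channel_labels Character vector of unique 10-20 labels, one per
#'   row of `data`. Defaults to [channels_1020()].
#' @param subject_id Subject identifier string.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, sampling_rate_hz,
                          channel_labels = channels_1020(),
                          subject_id = "subject") {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a positive scalar", call. = FALSE)
  }
  channel_labels <- as.character(channel_labels)
  if (nrow(data) != length(channel_labels)) {
    stop("number of rows of `data` must match `channel_labels`", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  if (length(channel_labels) != 19 ||
      !all(channel_labels %in% channels_1020())) {
    stop("expected exactly 19 channels drawn from the 10-20 label set",
         call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(
    list(
      data = data,
      sampling_rate_hz = sampling_rate_hz,
      channel_labels = channel_labels,
      subject_id = subject_id
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$sampling_rate_hz,
    ncol(x$data) / x$sampling_rate_hz
  ))
  invisible(x)
}

#' Epoched EEG data
#'
#' Epochs x channels x samples array plus the rejection bookkeeping that an
#' auditable artefact-rejection stage requires: `kept_mask` refers to the
#' original epoch indices, `rejection_log` records why each dropped epoch
#' was dropped.
#'
#' @param data Numeric array, epochs x channels x samples (µV), kept epochs
#'   only.
#' @param epoch_length_s Epoch length in seconds.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param channel_labels Channel labels (length = dim 2).
#' @param kept_mask Logical vector over the original epochs.
#' @param rejection_log Tibble with columns `epoch`, `reason`.
#' @param subject_id Subject identifier.
#' @return An `eeg_epochs` object.
#' @export
eeg_epochs <- function(data, epoch_length_s, sampling_rate_hz,
                       channel_labels = channels_1020(),
                       kept_mask = rep(TRUE, dim(data)[1]),
                       rejection_log = empty_rejection_log(),
                       subject_id = "subject") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  n_samp <- round(epoch_length_s * sampling_rate_hz)
  if (dim(data)[3] != n_samp) {
    stop("samples per epoch must equal round(epoch_length_s * sampling_rate_hz)",
         call. = FALSE)
  }
  if (dim(data)[1] != sum(kept_mask)) {
    stop("kept epoch count must equal sum(kept_mask)", call. = FALSE)
  }
  structure(
    list(
      data = data,
      epoch_length_s = epoch_length_s,
      sampling_rate_hz = sampling_rate_hz,
      channel_labels = as.character(channel_labels),
      kept_mask = kept_mask,
      rejection_log = rejection_log,
      subject_id = subject_id
    ),
    class = "eeg_epochs"
  )
}

empty_rejection_log <- function() {
  tibble::tibble(epoch = integer(), reason = character())
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %s: %d/%d epochs kept x %d channels x %d samples (%g s @ %g Hz)\n",
    x$subject_id, dim(x$data)[1], length(x$kept_mask), dim(x$data)[2],
    dim(x$data)[3], x$epoch_length_s, x$sampling_rate_hz
  ))
  if (nrow(x$rejection_log) > 0) {
    cat(sprintf("  rejected: %s\n",
                paste(x$rejection_log$epoch, collapse = ", ")))
  }
  invisible(x)
}

n_epochs <- function(ep) dim(ep$data)[1]
n_channels <- function(ep) dim(ep$data)[2]
n_samples <- function(ep) dim(ep$data)[3]

# Flatten kept epochs to a channels x (epochs*samples) matrix.
concat_epochs <- function(ep) {
  d <- aperm(ep$data, c(2, 3, 1)) # ch x samp x ep
  dim(d) <- c(dim(ep$data)[2], dim(ep$data)[3] * dim(ep$data)[1])
  rownames(d) <- ep$channel_labels
  d
}
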