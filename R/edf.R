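# Minimal EDF (European Data Format) I/O: standard 16-bit EDF, one data
# record per second. Covers what a resting-state clinical recording needs;
# no EDF+ annotations, no discontinuous records.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Writes standard 16-bit EDF with a 1 s data-record duration. The sampling
#' rate must therefore be a whole number of Hz, and a trailing partial
#' second of signal is dropped. Each channel is scaled to the full digital
#' range from its own physical min/max.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate_hz
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate (1 s data records)",
         call. = FALSE)
  }
  fs <- as.integer(round(fs))
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record", call. = FALSE)
  ns <- nrow(rec$data)
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]

  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L
  dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad_field(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr(rec$subject_id, 80)
  wr("doceeg synthetic resting-state EEG", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256L * (ns + 1L), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (lab in rec$channel_labels) wr(paste("EEG", lab), 16)
  for (i in seq_len(ns)) wr("AgAgCl cup electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in pmin_) wr(sprintf("%.6g", v), 8)
  for (v in pmax_) wr(sprintf("%.6g", v), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- x[, idx, drop = FALSE]
    dig <- round((block - pmin_) * scale + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    # EDF stores one channel after another within each record
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Minimal standard-EDF reader. Channel labels are matched
#' case-insensitively against the 10-20 set (an `EEG ` prefix and
#' reference suffixes such as `-A1A2` are tolerated); the channels are
#' returned in canonical montage order.
#'
#' @param path EDF file path.
#' @param subject_id Optional subject id; defaults to the patient-id header
#'   field.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8) # version
  patient <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80) # transducer
  for (i in seq_len(ns)) rd(8) # dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80) # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)

  out <- lapply(seq_len(ns), function(i) numeric(spr[i] * n_rec))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- (dig - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i]) +
        pmin_[i]
      out[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- phys
    }
  }

  canon <- match_1020_labels(labels)
  keep <- !is.na(canon)
  if (sum(keep) != 19) {
    stop(sprintf("EDF file maps onto %d of the 19 10-20 channels",
                 sum(keep)), call. = FALSE)
  }
  if (length(unique(spr[keep])) != 1) {
    stop("EEG channels must share one sampling rate", call. = FALSE)
  }
  ord <- order(match(canon[keep], channels_1020()))
  idx <- which(keep)[ord]
  data <- do.call(rbind, out[idx])
  eeg_recording(
    data = data,
    sampling_rate_hz = spr[idx[1]] / rec_dur,
    channel_labels = canon[idx],
    subject_id = subject_id %||% patient
  )
}

# Case-insensitive mapping of free-form EDF labels onto the 10-20 set.
match_1020_labels <- function(labels) {
  clean <- toupper(labels)
  clean <- sub("^EEG[ _]*", "", clean)
  clean <- sub("[-_ ].*$", "", clean)
  canon <- channels_1020()
  canon[match(clean, toupper(canon))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
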