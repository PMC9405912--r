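# Synthetic resting-state EEG cohorts with the statistical structure the
# downstream analysis assumes: per-channel 1/f background, a narrowband
# oscillator at a controllable dominant frequency, lagged phase coupling
# between designated electrode pairs (drives the weighted phase lag index),
# zero-lag broadband shared sources with subject-specific signed
# topographies (drive mutual information and coherence but not the wPLI),
# and occasional large-amplitude artefact epochs.

#' Subject-level generative profile
#'
#' All signal-level knobs for one synthetic subject. `coupling_strength`
#' interpolates, on each designated coupled pair, between an independent
#' oscillator on the receiving channel (0) and a pure quarter-cycle lagged
#' copy of the sending channel's oscillator (1), so the phase-lag index of
#' the pair rises from its null baseline towards 1.
#'
#' @param subject_id Identifier string.
#' @param etiology `"TBI"` or `"nonTBI"`.
#' @param outcome `"improved"` or `"nonimproved"`.
#' @param age_years Positive age in years.
#' @param dominant_freq_hz Oscillator frequency in Hz, inside the 1-30 Hz
#'   analysis band.
#' @param coupling_strength Lagged coupling in `[0, 1]`.
#' @param shared_source_gain Gain (>= 0) of the zero-lag broadband shared
#'   sources, in units of 8 µV source amplitude.
#' @param noise_gain Positive multiplier of the 20 µV 1/f background.
#' @param artefact_rate Per-second probability of an artefact excursion.
#' @param seed Integer RNG seed; the recording is bit-identical given the
#'   profile.
#' @return A `subject_profile` object (named list).
#' @export
subject_profile <- function(subject_id = "s01",
                            etiology = c("TBI", "nonTBI"),
                            outcome = c("nonimproved", "improved"),
                            age_years = 45,
                            dominant_freq_hz = 6,
                            coupling_strength = 0.4,
                            shared_source_gain = 1,
                            noise_gain = 1,
                            artefact_rate = 0,
                            seed = 1L) {
  etiology <- match.arg(etiology)
  outcome <- match.arg(outcome)
  if (dominant_freq_hz < 1 || dominant_freq_hz > 30) {
    stop("`dominant_freq_hz` must lie in the 1-30 Hz analysis band",
         call. = FALSE)
  }
  if (coupling_strength < 0 || coupling_strength > 1) {
    stop("`coupling_strength` must lie in [0, 1]", call. = FALSE)
  }
  if (shared_source_gain < 0) stop("`shared_source_gain` must be >= 0", call. = FALSE)
  if (noise_gain <= 0) stop("`noise_gain` must be positive", call. = FALSE)
  if (artefact_rate < 0 || artefact_rate > 1) {
    stop("`artefact_rate` must lie in [0, 1]", call. = FALSE)
  }
  if (age_years <= 0) stop("`age_years` must be positive", call. = FALSE)
  structure(
    list(
      subject_id = subject_id, etiology = etiology, outcome = outcome,
      age_years = age_years, dominant_freq_hz = dominant_freq_hz,
      coupling_strength = coupling_strength,
      shared_source_gain = shared_source_gain,
      noise_gain = noise_gain, artefact_rate = artefact_rate,
      seed = as.integer(seed)
    ),
    class = "subject_profile"
  )
}

#' Default coupled electrode pairs
#'
#' One lagged-coupled pair inside each connectivity ROI, so that raising
#' `coupling_strength` raises the ROI-summarised phase-lag index in all
#' five ROIs.
#'
#' @return Two-column character matrix (sender, receiver).
#' @export
default_coupled_pairs <- function() {
  rbind(
    c("F3", "P3"),   # left frontoparietal
    c("F4", "P4"),   # right frontoparietal
    c("F3", "F4"),   # frontal interhemispheric
    c("C3", "C4"),   # central interhemispheric
    c("P3", "P4")    # posterior interhemispheric
  )
}

# FFT-shaped Gaussian noise with amplitude spectrum ~ (1 + f)^(-1/2),
# scaled to unit variance.
one_over_f_noise <- function(n, fs) {
  freqs <- seq(0, fs / 2, by = fs / n)
  n_pos <- length(freqs)
  shape <- 1 / sqrt(1 + freqs)
  shape[1] <- 0 # no DC
  # Hermitian random spectrum
  amp <- stats::rnorm(n_pos) + 1i * stats::rnorm(n_pos)
  spec <- complex(real = 0, imaginary = 0)
  full <- rep(0 + 0i, n)
  full[seq_len(n_pos)] <- amp * shape
  if (n %% 2 == 0) full[n_pos] <- Re(full[n_pos]) # Nyquist real
  if (n_pos < n) full[(n_pos + 1):n] <- Conj(full[seq(n - n_pos + 1, 2)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Narrowband Gaussian oscillator at f0 (unit variance): Gaussian spectral
# window of width `bw_hz` filled with white complex spectrum (drawn
# directly in the frequency domain).
narrowband_oscillator <- function(n, fs, f0, bw_hz = 0.5) {
  freqs <- seq(0, fs, by = fs / n)[seq_len(n)]
  shape <- exp(-(freqs - f0)^2 / (2 * bw_hz^2))
  nz <- which(shape > 1e-12) # the window kills all other bins
  z <- complex(length.out = n)
  z[nz] <- stats::rnorm(length(nz)) + 1i * stats::rnorm(length(nz))
  x <- Re(stats::fft(z * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Quarter-cycle delay at f0 (rounded to whole samples).
quarter_cycle_lag <- function(x, fs, f0) {
  lag <- max(1L, round(fs / (4 * f0)))
  c(x[(lag + 1):length(x)], x[seq_len(lag)])
}

#' Generate one synthetic EEG recording
#'
#' Builds a 19-channel recording from a [subject_profile()]: per-channel
#' 1/f background (20 µV x `noise_gain`), a narrowband oscillator at the
#' subject's dominant frequency on every channel (15 µV), lagged mixing of
#' the sender oscillator into the receiver of each coupled pair, three
#' zero-lag broadband sources with per-channel signed Gaussian topographies
#' (8 µV x `shared_source_gain` each), and square-pulse + drift artefacts
#' (6x background SD) in randomly selected one-second segments.
#'
#' @param profile A [subject_profile()].
#' @param recording_length_s Recording duration in seconds.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param coupled_pairs Two-column matrix of (sender, receiver) labels;
#'   default [default_coupled_pairs()].
#' @param coupling_mode `"lagged"` (quarter-cycle delay; drives the wPLI) or
#'   `"zero_lag"` (volume-conduction control: same mixing without delay).
#' @param shared_channels Channels receiving the shared broadband sources;
#'   default all 19.
#' @return An [eeg_recording()].
#' @export
generate_subject_eeg <- function(profile,
                                 recording_length_s = 60,
                                 sampling_rate_hz = 500,
                                 coupled_pairs = default_coupled_pairs(),
                                 coupling_mode = c("lagged", "zero_lag"),
                                 shared_channels = channels_1020()) {
  stopifnot(inherits(profile, "subject_profile"))
  coupling_mode <- match.arg(coupling_mode)
  if (sampling_rate_hz <= 0) stop("sampling rate must be positive", call. = FALSE)
  chans <- channels_1020()
  if (!all(coupled_pairs %in% chans) || !all(shared_channels %in% chans)) {
    stop("coupled/shared channels must be 10-20 labels", call. = FALSE)
  }
  fs <- sampling_rate_hz
  n <- round(recording_length_s * fs)
  f0 <- profile$dominant_freq_hz

  local_seed(profile$seed)
  noise_sd <- 20 * profile$noise_gain
  osc_sd <- 15

  x <- matrix(0, nrow = 19, ncol = n, dimnames = list(chans, NULL))
  for (c_i in seq_len(19)) {
    x[c_i, ] <- noise_sd * one_over_f_noise(n, fs)
  }

  # intrinsic oscillators
  osc <- matrix(0, nrow = 19, ncol = n)
  for (c_i in seq_len(19)) {
    osc[c_i, ] <- narrowband_oscillator(n, fs, f0)
  }
  # lagged coupling: receiver oscillator interpolates towards a delayed
  # copy of the sender's oscillator
  cs <- profile$coupling_strength
  for (p in seq_len(nrow(coupled_pairs))) {
    i <- match(coupled_pairs[p, 1], chans)
    j <- match(coupled_pairs[p, 2], chans)
    src <- if (coupling_mode == "lagged") {
      quarter_cycle_lag(osc[i, ], fs, f0)
    } else {
      osc[i, ]
    }
    osc[j, ] <- (1 - cs) * osc[j, ] + cs * src
  }
  x <- x + osc_sd * osc

  # zero-lag broadband shared sources with signed random topographies
  if (profile$shared_source_gain > 0) {
    sel <- match(shared_channels, chans)
    for (k in 1:3) {
      src <- one_over_f_noise(n, fs)
      topo <- stats::rnorm(length(sel))
      x[sel, ] <- x[sel, ] +
        (profile$shared_source_gain * 8) * outer(topo, src)
    }
  }

  # artefacts: square pulse + drift, 6x background SD, on 4 random channels
  # of each affected one-second segment
  if (profile$artefact_rate > 0) {
    n_seg <- floor(n / fs)
    hit <- which(stats::runif(n_seg) < profile$artefact_rate)
    for (s in hit) {
      idx <- ((s - 1) * fs + 1):(s * fs)
      pulse_on <- idx[round(0.3 * fs):round(0.7 * fs)]
      ch_sel <- sample.int(19, 4)
      amp <- 6 * noise_sd
      for (ci in ch_sel) {
        x[ci, pulse_on] <- x[ci, pulse_on] + amp
        x[ci, idx] <- x[ci, idx] + seq(-amp / 2, amp / 2, length.out = length(idx))
      }
    }
  }

  eeg_recording(x, sampling_rate_hz = fs, channel_labels = chans,
                subject_id = profile$subject_id)
}

#' Cohort-level generative configuration
#'
#' Group structure of a synthetic cohort. Effects are parameterised as
#' between-group mean shifts of the subject-profile parameters:
#' `etiology_shift` is added/subtracted in halves to the non-TBI/TBI means,
#' `outcome_shift` likewise for improved/nonimproved. Setting every shift
#' to zero yields a null cohort.
#'
#' @param n_tbi,n_nontbi Group sizes (the emulated cohort is 15 TBI and 18
#'   non-TBI).
#' @param improved_fraction Length-2 vector (TBI, non-TBI) of improved
#'   fractions; defaults 8/15 and 5/18.
#' @param effects Named list of parameter effect settings; see
#'   [default_effects()].
#' @param recording_length_s Recording length in seconds (clinical sessions
#'   are 1200 s; simulation studies in this package use 60 s).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param artefact_rate Per-second artefact probability for every subject.
#' @param master_seed Integer seed from which all subject seeds derive.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_tbi = 15, n_nontbi = 18,
                          improved_fraction = c(8 / 15, 5 / 18),
                          effects = default_effects(),
                          recording_length_s = 1200,
                          sampling_rate_hz = 500,
                          artefact_rate = 0.05,
                          master_seed = 1L) {
  if (length(improved_fraction) == 1) {
    improved_fraction <- rep(improved_fraction, 2)
  }
  if (any(improved_fraction < 0 | improved_fraction > 1)) {
    stop("`improved_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (n_tbi < 0 || n_nontbi < 0) stop("group sizes must be >= 0", call. = FALSE)
  if (recording_length_s <= 0) stop("`recording_length_s` must be positive", call. = FALSE)
  structure(
    list(
      n_tbi = as.integer(n_tbi), n_nontbi = as.integer(n_nontbi),
      improved_fraction = improved_fraction,
      effects = utils::modifyList(default_effects(), effects),
      recording_length_s = recording_length_s,
      sampling_rate_hz = sampling_rate_hz,
      artefact_rate = artefact_rate,
      master_seed = as.integer(master_seed)
    ),
    class = "cohort_config"
  )
}

#' Default cohort effect settings
#'
#' Group effects follow the directions of the emulated study: slower
#' dominant frequency and weaker lagged coupling (wPLI) in TBI, stronger
#' shared broadband sources (mutual information, coherence) in improved
#' subjects. Shift magnitudes are chosen as ~1.7 between-subject SDs so a
#' cohort of 33 gives high screening power.
#'
#' @return Named list with one entry per generative parameter: `base`,
#'   `etiology_shift` (non-TBI minus TBI), `outcome_shift` (improved minus
#'   nonimproved), `sd`, and clipping `range`.
#' @export
default_effects <- function() {
  list(
    dominant_freq = list(base = 5.0, etiology_shift = 2.0,
                         outcome_shift = 0, sd = 1.2, range = c(3, 12)),
    coupling = list(base = 0.45, etiology_shift = 0.20,
                    outcome_shift = 0, sd = 0.12, range = c(0, 1)),
    shared_source = list(base = 1.125, etiology_shift = 0,
                         outcome_shift = 0.75, sd = 0.25, range = c(0, 5)),
    noise = list(base = 1, etiology_shift = 0, outcome_shift = 0,
                 sd = 0.15, range = c(0.4, 3))
  )
}

#' Null cohort effect settings (all shifts zero)
#' @return As [default_effects()] with every shift set to 0.
#' @export
null_effects <- function() {
  eff <- default_effects()
  for (nm in names(eff)) {
    eff[[nm]]$etiology_shift <- 0
    eff[[nm]]$outcome_shift <- 0
  }
  eff
}

draw_param <- function(spec, etiology, outcome) {
  m <- spec$base +
    ifelse(etiology == "nonTBI", 0.5, -0.5) * spec$etiology_shift +
    ifelse(outcome == "improved", 0.5, -0.5) * spec$outcome_shift
  v <- stats::rnorm(length(etiology), mean = m, sd = spec$sd)
  pmin(pmax(v, spec$range[1]), spec$range[2])
}

#' Generate a synthetic cohort
#'
#' Draws subject profiles and clinical records under a [cohort_config()]
#' and (optionally) the corresponding recordings. Outcome labels and GOS
#' scores are mutually consistent: `improved` if and only if
#' `gos_t1 - gos_t0 >= 1`. Per-subject seeds derive deterministically from
#' `master_seed`.
#'
#' @param config A [cohort_config()].
#' @param keep_recordings Generate and return the EEG recordings
#'   (memory-heavy for long recordings); profiles are always returned so
#'   recordings can be regenerated per subject.
#' @return List with `cohort` (tibble: subject_id, etiology, age_years,
#'   gcs_baseline, gos_t0, gos_t1, outcome, plus the injected generative
#'   parameters), `profiles` (list of [subject_profile()]), and
#'   `recordings` (list of [eeg_recording()] or `NULL`).
#' @export
generate_cohort <- function(config, keep_recordings = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_tbi + config$n_nontbi
  local_seed(config$master_seed)

  etiology <- c(rep("TBI", config$n_tbi), rep("nonTBI", config$n_nontbi))
  n_impr <- round(c(config$n_tbi, config$n_nontbi) * config$improved_fraction)
  outcome <- c(
    sample(rep(c("improved", "nonimproved"),
               c(n_impr[1], config$n_tbi - n_impr[1]))),
    sample(rep(c("improved", "nonimproved"),
               c(n_impr[2], config$n_nontbi - n_impr[2])))
  )

  age <- ifelse(etiology == "TBI",
                stats::rnorm(n, 34.3, 17.0),
                stats::rnorm(n, 49.1, 15.2))
  age <- pmin(pmax(age, 18), 80)
  gcs <- pmin(pmax(round(stats::rnorm(n, 4.5, 1.5)), 3), 15)
  gos_t0 <- sample(2:3, n, replace = TRUE)
  gos_t1 <- ifelse(outcome == "improved",
                   pmin(gos_t0 + sample(1:2, n, replace = TRUE), 5),
                   pmax(gos_t0 - sample(0:1, n, replace = TRUE), 1))

  eff <- config$effects
  dominant <- draw_param(eff$dominant_freq, etiology, outcome)
  coupling <- draw_param(eff$coupling, etiology, outcome)
  shared <- draw_param(eff$shared_source, etiology, outcome)
  noise <- draw_param(eff$noise, etiology, outcome)
  seeds <- sample.int(.Machine$integer.max - 1L, n)

  ids <- sprintf("s%02d", seq_len(n))
  # generative parameters carry a gen_ prefix so they never collide with
  # the measured feature columns of the same name
  cohort <- tibble::tibble(
    subject_id = ids, etiology = etiology, age_years = age,
    gcs_baseline = gcs, gos_t0 = gos_t0, gos_t1 = gos_t1,
    outcome = outcome,
    gen_dominant_freq_hz = dominant, gen_coupling_strength = coupling,
    gen_shared_source_gain = shared, gen_noise_gain = noise, seed = seeds
  )
  profiles <- purrr::map(seq_len(n), function(i) {
    subject_profile(
      subject_id = ids[i], etiology = etiology[i], outcome = outcome[i],
      age_years = age[i], dominant_freq_hz = dominant[i],
      coupling_strength = coupling[i],
      shared_source_gain = shared[i], noise_gain = noise[i],
      artefact_rate = config$artefact_rate, seed = seeds[i]
    )
  })
  recordings <- NULL
  if (keep_recordings) {
    recordings <- purrr::map(profiles, generate_subject_eeg,
                             recording_length_s = config$recording_length_s,
                             sampling_rate_hz = config$sampling_rate_hz)
  }
  list(cohort = cohort, profiles = profiles, recordings = recordings)
}

#' Derive the outcome label from GOS scores
#'
#' A subject counts as improved when the six-month GOS exceeds the
#' one-month GOS by at least one point.
#'
#' @param gos_t0,gos_t1 Integer GOS scores (1-5) at one and six months.
#' @return Character vector `"improved"` / `"nonimproved"`.
#' @export
outcome_from_gos <- function(gos_t0, gos_t1) {
  ifelse(gos_t1 - gos_t0 >= 1, "improved", "nonimproved")
}

#' Write a cohort to disk as EDF files plus a cohort CSV
#'
#' @param cohort_data Result of [generate_cohort()] (recordings present or
#'   regenerated from the profiles).
#' @param dir Output directory (created if needed).
#' @param recording_length_s,sampling_rate_hz Used when recordings must be
#'   regenerated from profiles.
#' @return `dir`, invisibly.
#' @export
write_cohort_edf <- function(cohort_data, dir,
                             recording_length_s = 60,
                             sampling_rate_hz = 500) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- cohort_data$recordings
  if (is.null(recs)) {
    recs <- purrr::map(cohort_data$profiles, generate_subject_eeg,
                       recording_length_s = recording_length_s,
                       sampling_rate_hz = sampling_rate_hz)
  }
  for (r in recs) write_edf(r, file.path(dir, paste0(r$subject_id, ".edf")))
  utils::write.csv(
    dplyr::select(cohort_data$cohort, "subject_id", "etiology", "age_years",
                  "gcs_baseline", "gos_t0", "gos_t1"),
    file.path(dir, "cohort.csv"), row.names = FALSE
  )
  invisible(dir)
}

# Seed the RNG locally, restoring the caller's RNG state on exit.
local_seed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    set.seed(seed)
    if (!is.null(old)) {
      withr::defer(assign(".Random.seed", old, envir = globalenv()),
                   envir = env)
    }
  }
  invisible(seed)
}
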