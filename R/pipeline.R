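# End-to-end orchestration: synthesize or load a cohort, preprocess,
# extract qEEG and connectivity features, screen biomarkers, classify
# outcome per etiology stratum, and write a versioned report.

#' Pipeline configuration
#'
#' Serialisable bundle of every stage parameter. Re-running with the same
#' configuration (and hence `master_seed`) reproduces every output.
#'
#' @param input `"synthetic"` or `"edf_directory"`.
#' @param cohort A [cohort_config()] (synthetic mode).
#' @param edf_dir Directory of EDF files plus `cohort.csv`
#'   (edf_directory mode).
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param target_rate_hz,band Resample/bandpass settings.
#' @param epoch_length_s Epoch length for qEEG/MI/coherence (1 s).
#' @param wpli_epoch_length_s Re-epoch length for the phase-lag stage (2 s).
#' @param abs_threshold_uv,sd_multiplier Artefact-rejection settings.
#' @param peen_m,peen_tau Permutation-entropy order and delay.
#' @param mi_bins Mutual-information histogram bins.
#' @param pad_ratio Coherence zero-padding factor.
#' @param n_surrogates,alpha wPLI surrogate-threshold settings.
#' @param n_cycles Morlet width.
#' @param wpli_freq_range Frequency clamp for the wPLI analysis frequency
#'   (a 6-cycle wavelet does not fit a 2 s epoch below ~3 Hz).
#' @param candidates Candidate features for the classification stage.
#' @param master_seed Integer master seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input = c("synthetic", "edf_directory"),
                            cohort = cohort_config(recording_length_s = 60),
                            edf_dir = NULL, out_dir = NULL,
                            target_rate_hz = 500, band = c(1, 30),
                            epoch_length_s = 1, wpli_epoch_length_s = 2,
                            abs_threshold_uv = 500, sd_multiplier = 3,
                            peen_m = 3, peen_tau = 1, mi_bins = 10,
                            pad_ratio = 8, n_surrogates = 200, alpha = 0.05,
                            n_cycles = 6, wpli_freq_range = c(3, 30),
                            candidates = c("dominant_freq_hz", "wpli_global",
                                           "mi_global", "pcoh_global"),
                            master_seed = 1L) {
  input <- match.arg(input)
  if (input == "edf_directory" && is.null(edf_dir)) {
    stop("`edf_dir` required for edf_directory input", call. = FALSE)
  }
  structure(
    list(input = input, cohort = cohort, edf_dir = edf_dir,
         out_dir = out_dir, target_rate_hz = target_rate_hz, band = band,
         epoch_length_s = epoch_length_s,
         wpli_epoch_length_s = wpli_epoch_length_s,
         abs_threshold_uv = abs_threshold_uv, sd_multiplier = sd_multiplier,
         peen_m = peen_m, peen_tau = peen_tau, mi_bins = mi_bins,
         pad_ratio = pad_ratio, n_surrogates = n_surrogates, alpha = alpha,
         n_cycles = n_cycles, wpli_freq_range = wpli_freq_range,
         candidates = candidates, master_seed = as.integer(master_seed)),
    class = "pipeline_config"
  )
}

#' Extract the full biomarker vector of one subject
#'
#' Runs the preprocessing, qEEG and connectivity stages on one recording:
#' resample + bandpass, 1 s epochs, artefact rejection, detrend, spectrum
#' (dominant frequency, z-scored band power), permutation entropy, mean
#' amplitude; then surface Laplacian, mutual information, coherence (at
#' the dominant frequency, plus full band), and the surrogate-thresholded
#' wPLI on 2 s epochs at the dominant frequency. Connectivity matrices are
#' summarised into the five ROIs plus the global mean.
#'
#' @param rec An [eeg_recording()].
#' @param config A [pipeline_config()].
#' @param surrogate_seed Seed for the wPLI surrogate null.
#' @return List: `features` (one-row tibble), `matrices` (named list of
#'   `connectivity_matrix`), `epochs_kept`, `rejection_log`.
#' @export
extract_subject_features <- function(rec, config = pipeline_config(),
                                     surrogate_seed = config$master_seed) {
  std <- standardize(rec, target_rate_hz = min(config$target_rate_hz,
                                               rec$sampling_rate_hz),
                     band = config$band)
  ep <- std |>
    epoch_eeg(config$epoch_length_s) |>
    reject_artifacts(config$abs_threshold_uv, config$sd_multiplier) |>
    detrend_epochs()

  qeeg <- qeeg_features(ep, band = config$band, peen_m = config$peen_m,
                        peen_tau = config$peen_tau)
  f0 <- qeeg$dominant_freq_hz

  lap <- laplacian_filter(ep)
  mi <- mutual_information_matrix(lap, n_bins = config$mi_bins)
  # coherence on the full signal (primary PCoh reading; a band average
  # needs no padded frequency grid) and at the individual dominant
  # frequency (pad ratio 8 for frequency resolution)
  pcoh <- coherence_matrix(lap, mode = "full_band", pad_ratio = 1,
                           band = config$band)
  pcoh_domfreq <- coherence_matrix(lap, mode = "at_frequency", freq_hz = f0,
                                   pad_ratio = config$pad_ratio,
                                   band = config$band)

  f0_wpli <- min(max(f0, config$wpli_freq_range[1]), config$wpli_freq_range[2])
  ep2 <- std |>
    laplacian_recording() |>
    epoch_eeg(config$wpli_epoch_length_s) |>
    reject_artifacts(config$abs_threshold_uv, config$sd_multiplier) |>
    detrend_epochs()
  wpli <- wpli_threshold(ep2, f0_wpli, n_surrogates = config$n_surrogates,
                         alpha = config$alpha, seed = surrogate_seed,
                         n_cycles = config$n_cycles)

  roi_row <- function(m, prefix) {
    r <- roi_summarize(m)
    names(r) <- paste0(prefix, "_", c(roi_names(), "global"))
    r
  }
  features <- dplyr::bind_cols(
    tibble::tibble(subject_id = rec$subject_id),
    qeeg,
    roi_row(wpli, "wpli"),
    roi_row(pcoh, "pcoh"),
    roi_row(mi, "mi"),
    tibble::tibble(
      pcoh_domfreq_global = roi_summarize(pcoh_domfreq)$global_mean
    )
  )
  list(
    features = features,
    matrices = list(wpli = wpli, pcoh = pcoh, pcoh_domfreq = pcoh_domfreq,
                    mi = mi),
    epochs_kept = sum(ep$kept_mask),
    rejection_log = ep$rejection_log
  )
}

# Laplacian re-reference applied to a continuous recording (linear,
# per-sample, so it commutes with epoching).
laplacian_recording <- function(rec, neighbors = laplacian_neighbors()) {
  labs <- rec$channel_labels
  nc <- length(labs)
  L <- diag(nc)
  for (ci in seq_len(nc)) {
    nb <- match(neighbors[[labs[ci]]], labs)
    L[ci, nb] <- -1 / length(nb)
  }
  out <- rec
  out$data <- L %*% rec$data
  rownames(out$data) <- labs
  out
}

#' Run the full study pipeline
#'
#' Synthesises (or loads) the cohort, extracts per-subject features,
#' screens biomarkers for etiology and outcome, and classifies outcome
#' within each etiology stratum with the stepwise diagonal LDA plus the
#' logistic control. Per-subject failures are logged and the subject is
#' excluded from all downstream tables; strata with fewer than 4 subjects
#' or a single outcome class skip classification with a notice. When
#' `config$out_dir` is set, writes `features.csv`,
#' `matrices/{subject}_{estimator}.csv`, per-subject
#' `rejection/{subject}.json` reports, `step1_report.json`,
#' `step2_{stratum}.json` and `provenance.json`.
#'
#' @param config A [pipeline_config()].
#' @param progress Print stage messages.
#' @return A `doc_run` list: `cohort`, `features`, `screen_etiology`,
#'   `screen_outcome`, `classification` (per-stratum), `excluded`,
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (progress) message(...)

  if (config$input == "synthetic") {
    gen <- generate_cohort(config$cohort)
    cohort <- gen$cohort
    profiles <- gen$profiles
    get_rec <- function(i) {
      generate_subject_eeg(profiles[[i]],
                           recording_length_s = config$cohort$recording_length_s,
                           sampling_rate_hz = config$cohort$sampling_rate_hz)
    }
    n_sub <- nrow(cohort)
  } else {
    cohort <- read_cohort_csv(file.path(config$edf_dir, "cohort.csv"))
    n_sub <- nrow(cohort)
    orig_ids <- cohort$subject_id
    get_rec <- function(i) {
      read_edf(file.path(config$edf_dir, paste0(orig_ids[i], ".edf")),
               subject_id = orig_ids[i])
    }
  }
  if (n_sub == 0) stop("empty input cohort", call. = FALSE)

  # exclude subjects with incomplete clinical records up front
  need <- c("gos_t0", "gos_t1", "etiology")
  bad_clin <- !stats::complete.cases(cohort[, need])
  excluded <- tibble::tibble(subject_id = cohort$subject_id[bad_clin],
                             reason = "incomplete clinical record")
  if (any(bad_clin)) {
    warning("excluding subjects with incomplete clinical records: ",
            paste(cohort$subject_id[bad_clin], collapse = ", "), call. = FALSE)
  }
  cohort <- cohort[!bad_clin, , drop = FALSE]
  if (!"outcome" %in% names(cohort)) {
    cohort$outcome <- outcome_from_gos(cohort$gos_t0, cohort$gos_t1)
  }

  say("extracting features for ", nrow(cohort), " subjects")
  sub_seeds <- config$master_seed + seq_len(n_sub)
  keep_idx <- which(!bad_clin)
  rows <- list()
  matrices <- list()
  rejections <- list()
  for (k in seq_along(keep_idx)) {
    i <- keep_idx[k]
    sid <- cohort$subject_id[k]
    res <- tryCatch(
      extract_subject_features(get_rec(i), config,
                               surrogate_seed = sub_seeds[i]),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warning("subject ", sid, " failed and is excluded: ",
              conditionMessage(res), call. = FALSE)
      excluded <- dplyr::bind_rows(
        excluded, tibble::tibble(subject_id = sid,
                                 reason = conditionMessage(res))
      )
      next
    }
    rows[[sid]] <- res$features
    matrices[[sid]] <- res$matrices
    rejections[[sid]] <- list(subject_id = sid,
                              epochs_kept = res$epochs_kept,
                              rejections = res$rejection_log)
  }
  features <- dplyr::bind_rows(rows)
  cohort <- cohort[cohort$subject_id %in% features$subject_id, , drop = FALSE]

  say("step-1 screening")
  screen_eti <- screen_biomarkers(features, cohort, factor = "etiology",
                                  alpha = config$alpha)
  screen_out <- screen_biomarkers(features, cohort, factor = "outcome",
                                  alpha = config$alpha)

  say("step-2 classification per etiology stratum")
  dat <- dplyr::inner_join(features, cohort, by = "subject_id")
  classification <- list()
  for (stratum in unique(dat$etiology)) {
    sub <- dat[dat$etiology == stratum, , drop = FALSE]
    if (nrow(sub) < 4 || length(unique(sub$outcome)) < 2 ||
        min(table(sub$outcome)) < 3) {
      classification[[stratum]] <- list(
        skipped = TRUE,
        notice = sprintf(
          "stratum %s skipped: %d subjects, classes %s", stratum, nrow(sub),
          paste(names(table(sub$outcome)), table(sub$outcome),
                sep = "=", collapse = ", ")
        )
      )
      next
    }
    search <- stepwise_search(sub, config$candidates)
    logit <- logistic_loo(sub, search$best$feature_subset)
    classification[[stratum]] <- list(skipped = FALSE, search = search,
                                      lda = search$best, logistic = logit)
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("doceeg")),
    master_seed = config$master_seed,
    input = config$input,
    n_subjects = nrow(features),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  run <- structure(
    list(cohort = cohort, features = features,
         screen_etiology = screen_eti, screen_outcome = screen_out,
         classification = classification, matrices = matrices,
         rejections = rejections,
         excluded = excluded, provenance = provenance, config = config),
    class = "doc_run"
  )
  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  run
}

read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort CSV not found: ", path, call. = FALSE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

write_run_outputs <- function(run, out_dir) {
  dir.create(file.path(out_dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.csv(run$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  for (sid in names(run$matrices)) {
    for (est in names(run$matrices[[sid]])) {
      write_connectivity_csv(
        run$matrices[[sid]][[est]],
        file.path(out_dir, "matrices", sprintf("%s_%s.csv", sid, est))
      )
    }
  }
  jsonlite::write_json(
    list(etiology = tidy(run$screen_etiology),
         outcome = tidy(run$screen_outcome)),
    file.path(out_dir, "step1_report.json"), auto_unbox = TRUE, digits = NA
  )
  dir.create(file.path(out_dir, "rejection"), showWarnings = FALSE)
  for (sid in names(run$rejections)) {
    jsonlite::write_json(run$rejections[[sid]],
                         file.path(out_dir, "rejection",
                                   paste0(sid, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  for (stratum in names(run$classification)) {
    cl <- run$classification[[stratum]]
    payload <- if (isTRUE(cl$skipped)) {
      list(skipped = TRUE, notice = cl$notice)
    } else {
      list(skipped = FALSE,
           best_features = cl$lda$feature_subset,
           lda = glance(cl$lda), logistic = glance(cl$logistic),
           ranking = cl$search$ranking,
           confusion = as.data.frame(as.table(cl$lda$confusion)),
           roc = cl$lda$roc_points)
    }
    jsonlite::write_json(payload,
                         file.path(out_dir, sprintf("step2_%s.json", stratum)),
                         auto_unbox = TRUE, digits = NA)
  }
  cfg <- run$config
  cfg$cohort <- unclass(cfg$cohort)
  jsonlite::write_json(
    c(run$provenance,
      list(config_hash = rlang::hash(unclass(cfg)))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' @export
print.doc_run <- function(x, ...) {
  cat(sprintf("<doc_run> %d subjects (%s input), seed %d\n",
              nrow(x$features), x$config$input, x$config$master_seed))
  cat("etiology biomarkers:",
      paste(x$screen_etiology$measure[x$screen_etiology$selected],
            collapse = ", "), "\n")
  cat("outcome biomarkers:",
      paste(x$screen_outcome$measure[x$screen_outcome$selected],
            collapse = ", "), "\n")
  for (stratum in names(x$classification)) {
    cl <- x$classification[[stratum]]
    if (isTRUE(cl$skipped)) {
      cat(stratum, ": ", cl$notice, "\n", sep = "")
    } else {
      cat(sprintf("%s: best {%s}, LOO accuracy %.1f%%\n", stratum,
                  paste(cl$lda$feature_subset, collapse = ", "),
                  100 * cl$lda$metrics$accuracy))
    }
  }
  invisible(x)
}

#' Replicate-cohort screening study
#'
#' Generates `n_cohorts` independent synthetic cohorts under one
#' configuration, runs the full pipeline's feature extraction and step-1
#' screening on each, and records which measures were selected for
#' etiology and outcome. Used for the power/selection-pattern properties
#' and by the acceptance analysis.
#'
#' @param n_cohorts Number of replicate cohorts.
#' @param config A [pipeline_config()]; its master seed is re-derived per
#'   replicate from `seed`.
#' @param seed Master seed for the study.
#' @param progress Print one line per cohort.
#' @return List: `selection` (tibble: cohort, factor, measure, selected,
#'   p), `first_run` (the `doc_run` of the first cohort, for step-2 use).
#' @export
simulate_screening_study <- function(n_cohorts = 50,
                                     config = pipeline_config(
                                       cohort = cohort_config(
                                         recording_length_s = 60,
                                         sampling_rate_hz = 250,
                                         master_seed = 1L),
                                       target_rate_hz = 250,
                                       n_surrogates = 50),
                                     seed = 1L, progress = FALSE) {
  sel <- list()
  first_run <- NULL
  for (r in seq_len(n_cohorts)) {
    cfg <- config
    cfg$master_seed <- as.integer(seed + 7919L * (r - 1L))
    cfg$cohort$master_seed <- cfg$master_seed
    cfg$out_dir <- NULL
    run <- run_pipeline(cfg)
    if (r == 1) first_run <- run
    grab <- function(scr, fac) {
      grp <- scr[scr$effect == "group", c("measure", "p", "selected")]
      dplyr::mutate(grp, cohort = r, factor = fac, .before = 1)
    }
    sel[[r]] <- dplyr::bind_rows(grab(run$screen_etiology, "etiology"),
                                 grab(run$screen_outcome, "outcome"))
    if (progress) {
      message(sprintf("cohort %d/%d done", r, n_cohorts))
    }
  }
  list(selection = dplyr::bind_rows(sel), first_run = first_run)
}

#' Permutation null for LOO accuracy
#'
#' Re-runs the LOO classifier on label-permuted copies of a feature table
#' to obtain the null distribution of accuracy.
#'
#' @param data,features,outcome_col,positive As [lda_loo()].
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Numeric vector of null accuracies.
#' @export
loo_permutation_null <- function(data, features, outcome_col = "outcome",
                                 positive = "nonimproved", n_perm = 200,
                                 seed = 1L) {
  local_seed(seed)
  vapply(seq_len(n_perm), function(i) {
    d <- data
    d[[outcome_col]] <- sample(d[[outcome_col]])
    while (min(table(d[[outcome_col]])) < 3) {
      d[[outcome_col]] <- sample(d[[outcome_col]])
    }
    lda_loo(d, features, outcome_col, positive)$metrics$accuracy
  }, numeric(1))
}
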