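# 10-20 montage: channel set, Laplacian neighbourhoods, ROI pair sets.

#' Standard 19-channel 10-20 labels
#'
#' The electrode set of a standard clinical EEG montage, in the canonical
#' anterior-to-posterior order used throughout the package.
#'
#' @return Character vector of 19 labels.
#' @export
#' @examples
#' channels_1020()
channels_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Nearest-neighbour adjacency for the surface Laplacian
#'
#' Versioned nearest-neighbour map on the 10-20 layout. Each electrode is
#' re-referenced against the mean of its listed neighbours by
#' [laplacian_filter()].
#'
#' @return Named list; one character vector of neighbour labels per channel.
#' @export
laplacian_neighbors <- function() {
  list(
    Fp1 = c("Fp2", "F7", "F3"),
    Fp2 = c("Fp1", "F4", "F8"),
    F7  = c("Fp1", "F3", "T3"),
    F3  = c("Fp1", "F7", "Fz", "C3"),
    Fz  = c("F3", "F4", "Cz"),
    F4  = c("Fp2", "F8", "Fz", "C4"),
    F8  = c("Fp2", "F4", "T4"),
    T3  = c("F7", "C3", "T5"),
    C3  = c("F3", "T3", "Cz", "P3"),
    Cz  = c("Fz", "C3", "C4", "Pz"),
    C4  = c("F4", "T4", "Cz", "P4"),
    T4  = c("F8", "C4", "T6"),
    T5  = c("T3", "P3", "O1"),
    P3  = c("C3", "T5", "Pz", "O1"),
    Pz  = c("Cz", "P3", "P4"),
    P4  = c("C4", "T6", "Pz", "O2"),
    T6  = c("T4", "P4", "O2"),
    O1  = c("T5", "P3", "O2"),
    O2  = c("T6", "P4", "O1")
  )
}

#' Region-of-interest electrode pairs
#'
#' The five connectivity ROIs: left and right frontoparietal
#' (intrahemispheric) and frontal, central and posterior interhemispheric.
#' Each ROI is the cross-product of a frontal/left set with a
#' parietal/right set; midline electrodes (Fz, Cz, Pz) are excluded.
#'
#' @return Tibble with columns `roi`, `ch1`, `ch2` (one row per electrode
#'   pair).
#' @export
#' @examples
#' dplyr::count(roi_pairs(), roi)
roi_pairs <- function() {
  cross <- function(roi, a, b) {
    tibble::tibble(
      roi = roi,
      ch1 = rep(a, each = length(b)),
      ch2 = rep(b, times = length(a))
    )
  }
  dplyr::bind_rows(
    cross("left_frontoparietal",  c("Fp1", "F3", "F7"), c("P3", "T5")),
    cross("right_frontoparietal", c("Fp2", "F4", "F8"), c("P4", "T6")),
    cross("frontal_inter",        c("Fp1", "F3", "F7"), c("Fp2", "F4", "F8")),
    cross("central_inter",        c("T3", "C3"),        c("C4", "T4")),
    cross("posterior_inter",      c("P3", "T5", "O1"),  c("P4", "T6", "O2"))
  )
}

roi_names <- function() {
  c("right_frontoparietal", "left_frontoparietal",
    "frontal_inter", "central_inter", "posterior_inter")
}
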