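#' Canonical EEG frequency band scheme
#'
#' The five-band partition of the 1--30 Hz range used throughout the
#' pipeline: delta 1--4 Hz, theta 4.5--7.5 Hz, alpha1 8--10 Hz, alpha2
#' 10.5--12.5 Hz, beta 13--30 Hz. Intervals are closed at both ends; at the
#' pipeline's 0.5 Hz spectral resolution the bands partition the frequency
#' bins from 1.0 to 30.0 Hz exactly (7 + 7 + 5 + 5 + 35 = 59 bins), so the
#' half-bin gaps between the printed interval ends are unambiguous.
#'
#' @return A data frame with columns `band`, `lo`, `hi` (Hz).
#' @export
#' @examples
#' band_scheme()
band_scheme <- function() {
  data.frame(
    band = c("delta", "theta", "alpha1", "alpha2", "beta"),
    lo = c(1, 4.5, 8, 10.5, 13),
    hi = c(4, 7.5, 10, 12.5, 30),
    stringsAsFactors = FALSE
  )
}

#' Slow/fast classification of EEG bands for stimulation frequency choice
#'
#' Bands whose excess triggers 30 Hz beta-tACS (slow: delta, theta, alpha1)
#' versus 4 Hz theta-tACS (fast: alpha2, beta).
#'
#' @param band Character vector of band names.
#' @return Character vector, `"slow"` or `"fast"` for each band.
#' @export
band_class <- function(band) {
  band <- tolower(band)
  known <- band_scheme()$band
  if (!all(band %in% known))
    stop("unknown band(s): ", paste(setdiff(band, known), collapse = ", "),
         call. = FALSE)
  ifelse(band %in% c("delta", "theta", "alpha1"), "slow", "fast")
}

#' Default 32-electrode 10/10 montage
#'
#' Standard 32-channel cap layout (10/10 positions) used by the synthetic
#' generator and fixtures. Contains all electrodes referenced by the default
#' region-of-interest scheme.
#'
#' @return Character vector of 32 electrode labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8",
    "PO9", "O1", "Oz", "O2", "PO10")
}

#' Default region-of-interest electrode sets
#'
#' Six scalp regions used for group-level band-power aggregation:
#' frontal, motor and parietal areas on each hemisphere.
#'
#' @return Named list of character vectors of electrode labels.
#' @export
#' @examples
#' roi_scheme()$left_motor
roi_scheme <- function() {
  list(
    left_frontal   = c("Fp1", "F7", "F3"),
    right_frontal  = c("Fp2", "F8", "F4"),
    left_motor     = c("FC1", "FC5", "C3", "CP1"),
    right_motor    = c("FC2", "FC6", "C4", "CP2"),
    left_parietal  = c("CP5", "P7", "P3"),
    right_parietal = c("CP6", "P8", "P4")
  )
}
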