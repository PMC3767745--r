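#' Standard 18-electrode montage for network construction
#'
#' The widely spaced 10-20 electrode subset used as network nodes:
#' Fp1, Fp2, F7, F3, Fz, F4, F8, T3, C3, C4, T4, T5, P3, Pz, P4, T6, O1, O2.
#' Wide spacing limits volume-conduction leakage between neighbouring
#' sensors, which would otherwise inflate scalp coherence.
#'
#' @return Character vector of 18 electrode labels, frontal to occipital.
#' @examples
#' ssvep_montage()
#' @export
ssvep_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Fundamental stimulus frequency from a flicker cycle duration
#'
#' A periodic visual stimulus with cycle duration `cycle_ms` milliseconds
#' drives a steady-state response at the fundamental `1000 / cycle_ms` Hz
#' (an 80 ms cycle gives 12.5 Hz, a 60 ms cycle gives 16.67 Hz).
#'
#' @param cycle_ms Flicker cycle duration in milliseconds (> 0).
#' @return Fundamental frequency in Hz.
#' @examples
#' stim_frequency(80) # 12.5 Hz
#' stim_frequency(60) # 16.67 Hz
#' @export
stim_frequency <- function(cycle_ms) {
  if (!is.numeric(cycle_ms) || any(cycle_ms <= 0)) {
    stop("'cycle_ms' must be a positive duration in milliseconds")
  }
  1000 / cycle_ms
}

## canonical label for a stimulus condition, used in reports and file names
condition_label <- function(stim_freq) {
  sprintf("%.1fHz", stim_freq)
}
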