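# Per-trial peak beta frequency and endogenous-exogenous differences.

#' Peak beta frequency of a baseline-corrected connectivity profile
#'
#' Given per-frequency, baseline-subtracted values already averaged over a
#' movement period, returns the beta-band frequency with the greatest
#' absolute deviation (the frequency showing the strongest ERD- or ERS-like
#' change in the connectivity map). Ties break toward the lower frequency.
#' The choice depends only on the ordering of `|values|`, so it is invariant
#' to any strictly monotone rescaling of the magnitudes.
#'
#' @param values Numeric vector of baseline-subtracted values, one per
#'   frequency bin.
#' @param freqs Frequencies in Hz matching `values`.
#' @param band Beta band edges, inclusive. Default `c(13, 30)`.
#' @return Peak frequency in Hz.
#' @export
peak_beta <- function(values, freqs, band = c(13, 30)) {
  stopifnot(length(values) == length(freqs))
  sel <- which(freqs >= band[1L] & freqs <= band[2L])
  if (length(sel) == 0L) stop("no beta-band frequency bins present",
                              call. = FALSE)
  v <- abs(values[sel])
  if (all(is.na(v))) stop("all beta-band values missing", call. = FALSE)
  ord <- order(freqs[sel])
  sel <- sel[ord]; v <- v[ord]
  freqs[sel[which.max(v)]]   # which.max takes the first (lowest) on ties
}

#' Endogenous-exogenous frequency difference
#'
#' Peak beta frequency minus the 20 Hz stimulation frequency.
#'
#' @param peak_hz Peak beta frequency in Hz.
#' @param stim_hz Stimulation frequency. Default 20.
#' @return `peak_hz - stim_hz` (Hz).
#' @export
endo_exo_diff <- function(peak_hz, stim_hz = 20) {
  peak_hz - stim_hz
}
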