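# Preprocessing: zero-phase filtering, resampling, onset detection,
# epoching, artifact rejection and average re-referencing.

# Linear-phase FIR for the combined band-pass + notch, applied zero-phase by
# centred FFT convolution (symmetric kernel => exactly zero phase). The
# frequency-sampling design (signal::fir2, Hamming window) uses a 0.5 Hz
# transition at the high-pass edge, so the kernel is long (~6.6 s at
# 1000 Hz); recordings, not epochs, are filtered.
bandpass_notch_kernel <- function(rate, low, high, notch, ntaps = NULL) {
  nyq <- rate / 2
  if (is.null(ntaps)) {
    ntaps <- as.integer(round(3.3 / (low / 2) * rate))
    if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  }
  f <- c(0, low / 2, low * 1.5, notch - 2.5, notch - 0.75,
         notch + 0.75, notch + 2.5, high * 0.95, high * 1.02, nyq)
  m <- c(0, 0, 1, 1, 0, 0, 1, 1, 0, 0)
  keep <- !duplicated(f)
  signal::fir2(ntaps - 1L, f[keep] / nyq, m[keep])
}

#' Band-pass and notch filter a recording
#'
#' Zero-phase filtering of all EEG channels: band-pass `low`-`high` Hz plus a
#' notch at the mains frequency. Implemented as a single linear-phase FIR
#' kernel applied by centred FFT convolution, so the output has exactly zero
#' phase shift and filtering is linear. The force channel, if any, is left
#' untouched.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band edges in Hz. Defaults 0.5 and 95.
#' @param notch Notch centre in Hz. Default 50.
#' @return The filtered `eeg_recording`.
#' @export
bandpass_notch <- function(rec, low = 0.5, high = 95, notch = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate <= 2 * high) {
    stop(sprintf("sampling rate %g Hz too low for a %g Hz band edge",
                 rec$rate, high), call. = FALSE)
  }
  h <- bandpass_notch_kernel(rec$rate, low, high, notch)
  n <- ncol(rec$data)
  nfft <- stats::nextn(n + length(h) - 1L, c(2L, 3L))
  H <- kernel_spectrum(h, nfft)
  pad <- numeric(nfft - n)
  for (k in seq_len(nrow(rec$data))) {
    xp <- c(rec$data[k, ], pad)
    y <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE)) / nfft
    rec$data[k, ] <- y[seq_len(n)]
  }
  rec$filter <- list(low = low, high = high, notch = notch, ntaps = length(h))
  rec
}

# Fourier-domain downsampling to m samples: exact unit passband gain and a
# brick-wall anti-alias cutoff at the new Nyquist frequency.
fft_downsample <- function(x, m) {
  n <- length(x)
  X <- stats::fft(x)
  half <- if (m %% 2L == 0L) m %/% 2L - 1L else (m - 1L) %/% 2L
  Y <- complex(m)
  Y[1L] <- X[1L]
  if (half > 0L) {
    Y[2L:(half + 1L)] <- X[2L:(half + 1L)]
    Y[(m - half + 1L):m] <- X[(n - half + 1L):n]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample a recording
#'
#' Anti-aliased resampling of every channel (and the force channel) to
#' `target` Hz by Fourier-domain truncation: passband amplitudes are
#' preserved exactly and content above the new Nyquist frequency is removed
#' with a brick-wall cutoff. Onset times are stored in seconds and
#' therefore re-index exactly.
#'
#' @param rec An `eeg_recording`.
#' @param target Target rate in Hz (<= current rate). Default 500.
#' @return The resampled `eeg_recording`.
#' @export
resample_recording <- function(rec, target = 500) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target > rec$rate) stop("`target` must not exceed the current rate",
                              call. = FALSE)
  if (target == rec$rate) return(rec)
  n <- ncol(rec$data)
  m <- as.integer(round(n * target / rec$rate))
  new <- t(apply(rec$data, 1L, fft_downsample, m = m))
  rownames(new) <- rownames(rec$data)
  rec$data <- new
  if (!is.null(rec$force)) rec$force <- fft_downsample(rec$force, m)
  rec$rate <- target
  rec
}

#' Detect movement onsets from a force trace
#'
#' One onset per supra-threshold excursion, at the first sample at which the
#' force exceeds `threshold`; a refractory period suppresses re-triggers
#' within the same press.
#'
#' @param force Numeric force trace.
#' @param threshold Force threshold (same units as `force`); must exceed the
#'   baseline noise level.
#' @param rate Sampling rate of `force`, Hz.
#' @param refractory_ms Minimum spacing between onsets, ms. Default 2000.
#' @return Integer vector of onset sample indices (possibly empty).
#' @export
detect_onsets <- function(force, threshold, rate, refractory_ms = 2000) {
  if (length(force) == 0L) stop("empty force trace", call. = FALSE)
  stopifnot(is.finite(threshold))
  cross <- which(diff(c(FALSE, force > threshold)) == 1L)
  if (length(cross) == 0L) return(integer(0))
  refr <- refractory_ms / 1000 * rate
  keep <- cross[1L]
  for (s in cross[-1L]) if (s - keep[length(keep)] >= refr) keep <- c(keep, s)
  as.integer(keep)
}

#' Cut a recording into epochs
#'
#' Resting mode divides the recording into contiguous, non-overlapping
#' segments of `resting_len_ms` (default 2000 ms) from the recording start;
#' a trailing partial segment is dropped. Event mode cuts one epoch per
#' onset spanning `event_window` (default -2500 to 4500 ms, half-open in
#' samples); epochs that would extend past either end of the recording are
#' dropped. The force channel is not epoched.
#'
#' @param rec An `eeg_recording`.
#' @param mode `"resting"` or `"event"`.
#' @param onsets Event mode: onset sample indices. Defaults to the
#'   recording's stored onset times.
#' @param resting_len_ms Resting segment length, ms.
#' @param event_window Event epoch window `c(start, end)` in ms relative to
#'   onset.
#' @return An `eeg_epochs` object: `data` (trials x channels x samples),
#'   `rate`, `t0` (ms of the first sample relative to the event; 0 for
#'   resting), `channel_labels`, `trial_meta`, `rejected`.
#' @export
epoch_recording <- function(rec, mode = c("resting", "event"), onsets = NULL,
                            resting_len_ms = 2000,
                            event_window = c(-2500, 4500)) {
  stopifnot(inherits(rec, "eeg_recording"))
  mode <- match.arg(mode)
  n <- ncol(rec$data); nch <- nrow(rec$data); rate <- rec$rate
  if (mode == "resting") {
    len <- as.integer(round(resting_len_ms / 1000 * rate))
    if (n < len) stop("recording shorter than one epoch", call. = FALSE)
    n_ep <- n %/% len
    starts <- (seq_len(n_ep) - 1L) * len + 1L
    t0 <- 0
  } else {
    if (is.null(onsets)) {
      if (is.null(rec$onsets)) stop("event mode requires onsets",
                                    call. = FALSE)
      onsets <- as.integer(round(rec$onsets * rate)) + 1L
    }
    len <- as.integer(round((event_window[2L] - event_window[1L]) / 1000 * rate))
    starts <- as.integer(onsets) +
      as.integer(round(event_window[1L] / 1000 * rate))
    ok <- starts >= 1L & (starts + len - 1L) <= n
    starts <- starts[ok]
    if (length(starts) == 0L) stop("no onset leaves a complete epoch inside the recording",
                                   call. = FALSE)
    t0 <- event_window[1L]
  }
  n_ep <- length(starts)
  data <- array(0, dim = c(n_ep, nch, len))
  for (k in seq_len(n_ep)) {
    data[k, , ] <- rec$data[, starts[k] + seq_len(len) - 1L]
  }
  meta <- data.frame(trial = seq_len(n_ep))
  for (nm in names(rec$meta)) meta[[nm]] <- rec$meta[[nm]]
  structure(list(data = data, rate = rate, t0 = t0,
                 channel_labels = rec$channel_labels,
                 trial_meta = meta, mode = mode,
                 rejected = rep(FALSE, n_ep),
                 reject_reason = rep(NA_character_, n_ep)),
            class = "eeg_epochs")
}

#' Peak-to-peak artifact rejection and average re-referencing
#'
#' Flags every trial whose peak-to-peak amplitude on any channel exceeds
#' `ptp_limit`, then re-references all trials to the instantaneous
#' cross-channel average (the mean over channels at every sample becomes 0).
#' If fewer than `min_trials` trials survive, a classed warning
#' (`imcoh_participant_excluded`) is raised and the result is marked
#' excluded, mirroring the minimum-trial rule used when deciding whether a
#' participant's block is usable.
#'
#' @param epochs An `eeg_epochs`.
#' @param ptp_limit Peak-to-peak limit in microvolts (> 0). Default 200.
#' @param min_trials Minimum surviving trials before the block is flagged
#'   for exclusion. Default 20.
#' @return The `eeg_epochs` with updated `rejected` flags, re-referenced
#'   data, and attribute `excluded`.
#' @export
reject_and_reference <- function(epochs, ptp_limit = 200, min_trials = 20) {
  stopifnot(inherits(epochs, "eeg_epochs"), ptp_limit > 0)
  nt <- dim(epochs$data)[1L]
  ptp <- vapply(seq_len(nt), function(k) {
    x <- epochs$data[k, , , drop = FALSE]
    max(apply(x[1L, , , drop = TRUE], 1L, function(ch) diff(range(ch))))
  }, numeric(1))
  newly <- ptp > ptp_limit
  epochs$reject_reason[newly & !epochs$rejected] <-
    sprintf("ptp %.1f > %.1f", ptp[newly & !epochs$rejected], ptp_limit)
  epochs$rejected <- epochs$rejected | newly
  if (all(epochs$rejected)) stop("all trials rejected", call. = FALSE)
  # average reference: subtract the cross-channel mean at every sample
  for (k in seq_len(nt)) {
    x <- epochs$data[k, , ]
    epochs$data[k, , ] <- x - rep(colMeans(x), each = nrow(x))
  }
  n_surv <- sum(!epochs$rejected)
  excluded <- n_surv < min_trials
  attr(epochs, "excluded") <- excluded
  attr(epochs, "n_surviving") <- n_surv
  if (excluded) {
    warning(structure(
      class = c("imcoh_participant_excluded", "warning", "condition"),
      list(message = sprintf(
        "only %d trials survive rejection (minimum %d): block flagged for exclusion",
        n_surv, min_trials), call = NULL)))
  }
  epochs
}

#' Keep a subset of channels
#'
#' @param epochs An `eeg_epochs`.
#' @param labels Channel labels to keep, in the given order.
#' @return The subsetted `eeg_epochs`.
#' @export
select_channels <- function(epochs, labels) {
  idx <- match(labels, epochs$channel_labels)
  if (anyNA(idx)) stop("unknown channel label(s): ",
                       paste(labels[is.na(idx)], collapse = ", "),
                       call. = FALSE)
  epochs$data <- epochs$data[, idx, , drop = FALSE]
  epochs$channel_labels <- labels
  epochs
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$mode, d[1L], d[2L], d[3L], x$rate))
  cat(sprintf("  t0 = %g ms; %d trial(s) rejected\n", x$t0, sum(x$rejected)))
  invisible(x)
}
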