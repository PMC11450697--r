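# Complex Morlet wavelet time-frequency decomposition.

#' Build the Morlet wavelet bank
#'
#' Frequencies from `fmin` to `fmax` in `step` Hz increments (the default
#' grid, 4-90 Hz in 1 Hz steps, has 87 frequencies). Wavelet length in
#' cycles increases geometrically over the frequency index from
#' `cycles_min` at the lowest frequency to `cycles_max` at the highest:
#' `cycles[k] = exp(log(c_min) + (log(c_max) - log(c_min)) * k / (n - 1))`.
#' The temporal standard deviation of each wavelet's Gaussian envelope is
#' `sigma_t = cycles / (2 * pi * f)` seconds.
#'
#' @param fmin,fmax,step Frequency grid in Hz. Defaults 4, 90, 1.
#' @param cycles_min,cycles_max Cycle counts at the grid endpoints.
#'   Defaults 3 and 13.
#' @return A `wavelet_bank`: list with `freqs`, `cycles`, `sigma_t`.
#' @export
build_wavelet_bank <- function(fmin = 4, fmax = 90, step = 1,
                               cycles_min = 3, cycles_max = 13) {
  stopifnot(fmin > 0, fmax > fmin, step > 0, cycles_min > 0,
            cycles_max >= cycles_min)
  freqs <- seq(fmin, fmax, by = step)
  n <- length(freqs)
  cycles <- if (n == 1L) cycles_min else
    exp(seq(log(cycles_min), log(cycles_max), length.out = n))
  # pin the endpoints exactly (exp(log(x)) can be off by one ulp)
  cycles[1L] <- cycles_min
  cycles[n] <- cycles_max
  structure(list(freqs = freqs, cycles = cycles,
                 sigma_t = cycles / (2 * pi * freqs)),
            class = "wavelet_bank")
}

#' Standard analysis time grids
#'
#' 20 ms grids used for the resting-state window (400-1600 ms within each
#' 2 s epoch, 61 points, chosen to keep every point clear of epoch-edge
#' artifacts), the event-related window of interest (-500 to 4000 ms, 226
#' points), the pre-movement baseline (-2000 to -1000 ms) and the combined
#' event grid covering baseline plus window of interest.
#'
#' @param window One of `"resting"`, `"event"`, `"baseline"`, `"event_full"`.
#' @param step_ms Grid step in ms. Default 20.
#' @return Numeric vector of times in ms.
#' @export
tfr_grid <- function(window = c("resting", "event", "baseline", "event_full"),
                     step_ms = 20) {
  window <- match.arg(window)
  lim <- switch(window,
                resting = c(400, 1600),
                event = c(-500, 4000),
                baseline = c(-2000, -1000),
                event_full = c(-2000, 4000))
  seq(lim[1L], lim[2L], by = step_ms)
}

# Sampled complex Morlet wavelet, truncated at +/- 5 sigma_t, normalized so
# that a unit-amplitude real sinusoid at f yields |x(f)| = 1.
morlet_kernel <- function(f, sigma_t, rate) {
  half <- as.integer(ceiling(5 * sigma_t * rate))
  tt <- (-half:half) / rate
  g <- exp(-tt^2 / (2 * sigma_t^2))
  w <- exp(2i * pi * f * tt) * g
  w * (2 / sum(g))
}

#' Complex Morlet wavelet transform of an epoch set
#'
#' Convolves every trial and channel with the wavelet bank (frequency-domain
#' multiplication after symmetric zero padding; equal to direct convolution
#' to numerical precision) and samples the complex analytic values at the
#' requested time grid. A grid point is considered edge-clean at a given
#' frequency when it lies at least `3 * sigma_t` from both epoch edges; the
#' logical matrix of clean cells is returned in attribute `edge_ok`, and a
#' warning is emitted if any requested cell is not clean.
#'
#' @param epochs An `eeg_epochs` (rejected trials are dropped here).
#' @param bank A [build_wavelet_bank()].
#' @param times Time grid in ms (relative to the epoch's `t0` frame); see
#'   [tfr_grid()].
#' @return An `eeg_tfr`: complex array `trials x channels x freqs x times`
#'   plus `freqs`, `times`, `channel_labels`, `trial_meta`.
#' @export
tfr_transform <- function(epochs, bank = build_wavelet_bank(),
                          times = tfr_grid("resting")) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(bank, "wavelet_bank"))
  keep <- which(!epochs$rejected)
  if (length(keep) == 0L) stop("no surviving trials", call. = FALSE)
  data <- epochs$data[keep, , , drop = FALSE]
  if (anyNA(data)) stop("NaN/NA in input epochs", call. = FALSE)
  rate <- epochs$rate
  nt <- dim(data)[1L]; nch <- dim(data)[2L]; ns <- dim(data)[3L]
  nf <- length(bank$freqs)
  idx <- as.integer(round((times - epochs$t0) / 1000 * rate)) + 1L
  if (any(idx < 1L | idx > ns)) stop("time grid outside epoch", call. = FALSE)

  # edge-cleanliness per (frequency, grid point)
  t_samp <- (idx - 1L) / rate
  epoch_len <- ns / rate
  edge_ok <- outer(3 * bank$sigma_t, t_samp,
                   function(s, tc) tc >= s & (epoch_len - tc) >= s)
  dimnames(edge_ok) <- NULL
  if (!all(edge_ok)) {
    warning(sprintf("%d of %d (frequency, time) cells are within 3*sigma_t of an epoch edge",
                    sum(!edge_ok), length(edge_ok)), call. = FALSE)
  }

  max_half <- as.integer(ceiling(5 * max(bank$sigma_t) * rate))
  nfft <- stats::nextn(ns + 2L * max_half, c(2L, 3L))
  W <- matrix(0i, nrow = nfft, ncol = nf)
  for (j in seq_len(nf)) {
    W[, j] <- kernel_spectrum(morlet_kernel(bank$freqs[j], bank$sigma_t[j],
                                            rate), nfft)
  }
  vals <- array(0i, dim = c(nt, nch, nf, length(idx)))
  pad <- numeric(nfft - ns)
  for (k in seq_len(nt)) {
    for (c in seq_len(nch)) {
      X <- stats::fft(c(data[k, c, ], pad))
      Y <- stats::mvfft(W * X, inverse = TRUE) / nfft
      vals[k, c, , ] <- t(Y[idx, , drop = FALSE])
    }
  }
  structure(list(values = vals, freqs = bank$freqs, times = times,
                 channel_labels = epochs$channel_labels,
                 trial_meta = epochs$trial_meta[keep, , drop = FALSE],
                 rate = rate, bank = bank),
            class = "eeg_tfr", edge_ok = edge_ok)
}

#' @export
print.wavelet_bank <- function(x, ...) {
  cat(sprintf("<wavelet_bank> %d frequencies %g-%g Hz, %.3g-%.3g cycles\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              x$cycles[1L], x$cycles[length(x$cycles)]))
  invisible(x)
}

#' @export
print.eeg_tfr <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<eeg_tfr> %d trials x %d channels x %d freqs x %d times\n",
              d[1L], d[2L], d[3L], d[4L]))
  cat(sprintf("  freqs %g-%g Hz; times %g-%g ms\n", min(x$freqs),
              max(x$freqs), min(x$times), max(x$times)))
  invisible(x)
}
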