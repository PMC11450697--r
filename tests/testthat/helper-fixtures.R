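# Shared fixtures and independent oracles for the test suite.

# Build an eeg_epochs object directly from a trials x channels x samples
# array (bypassing the generator) for constructed-signal tests.
make_epochs <- function(data, rate = 500, t0 = 0,
                        labels = paste0("ch", seq_len(dim(data)[2L]))) {
  structure(list(data = data, rate = rate, t0 = t0,
                 channel_labels = labels,
                 trial_meta = data.frame(trial = seq_len(dim(data)[1L])),
                 mode = "resting",
                 rejected = rep(FALSE, dim(data)[1L]),
                 reject_reason = rep(NA_character_, dim(data)[1L])),
            class = "eeg_epochs")
}

# Epochs holding two sinusoidal channels with a fixed phase lag of `lag`
# radians (channel 2 lags channel 1), random carrier phase per trial.
make_lagged_epochs <- function(n_trials, lag, f = 20, rate = 500,
                               n_samp = 1000, seed = 1) {
  set.seed(seed)
  tt <- (seq_len(n_samp) - 1L) / rate
  data <- array(0, c(n_trials, 2L, n_samp))
  for (k in seq_len(n_trials)) {
    th <- stats::runif(1, -pi, pi)
    data[k, 1L, ] <- cos(2 * pi * f * tt + th)
    data[k, 2L, ] <- cos(2 * pi * f * tt + th + lag)
  }
  make_epochs(data, rate = rate, labels = c("a", "b"))
}

# Build a bare eeg_tfr from a complex array (trials x channels x freqs x
# times) for estimator identity tests.
make_tfr <- function(values, freqs, times,
                     labels = paste0("ch", seq_len(dim(values)[2L]))) {
  structure(list(values = values, freqs = freqs, times = times,
                 channel_labels = labels,
                 trial_meta = data.frame(trial = seq_len(dim(values)[1L])),
                 rate = 500, bank = NULL),
            class = "eeg_tfr")
}

# Plain recording wrapper around a channels x samples matrix.
make_recording <- function(data, rate = 1000, force = NULL, onsets = NULL,
                           labels = rownames(data) %||%
                             paste0("ch", seq_len(nrow(data)))) {
  structure(list(data = data, rate = rate, channel_labels = labels,
                 force = force, onsets = onsets, meta = list()),
            class = "eeg_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -------------------------------------------------

# Spearman rho by the textbook rank-difference formula (valid without ties).
spearman_d2_oracle <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Mean resultant length of the von Mises distribution by direct numerical
# integration (independent of besselI).
vm_resultant_oracle <- function(kappa) {
  if (is.infinite(kappa)) return(1)
  if (kappa == 0) return(0)
  num <- stats::integrate(function(th) cos(th) * exp(kappa * cos(th)),
                          -pi, pi)$value
  den <- stats::integrate(function(th) exp(kappa * cos(th)), -pi, pi)$value
  num / den
}

# Recursive flood-fill connected components (4-neighbour, same sign),
# written independently of the package's iterative implementation.
# Returns a list of clusters as sorted cell-index vectors plus masses.
floodfill_oracle <- function(supra, rho) {
  nr <- nrow(supra); nc <- ncol(supra)
  seen <- matrix(FALSE, nr, nc)
  out <- list()
  fill <- function(i, j, s) {
    if (i < 1 || i > nr || j < 1 || j > nc) return(integer(0))
    if (seen[i, j] || !supra[i, j] || sign(rho[i, j]) != s) return(integer(0))
    seen[i, j] <<- TRUE
    c((j - 1L) * nr + i,
      fill(i - 1L, j, s), fill(i + 1L, j, s),
      fill(i, j - 1L, s), fill(i, j + 1L, s))
  }
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (supra[i, j] && !seen[i, j]) {
      cells <- sort(fill(i, j, sign(rho[i, j])))
      out[[length(out) + 1L]] <- list(cells = cells,
                                      mass = sum(abs(rho[cells])))
    }
  }
  out
}

# Canonical form of the package's cluster list for comparison with the
# oracle: sorted linear cell indices per cluster, sorted by first cell.
canon_clusters <- function(clusters, nr) {
  lst <- lapply(clusters, function(cl) {
    sort(as.integer((cl$cells[, 2L] - 1L) * nr + cl$cells[, 1L]))
  })
  ord <- order(vapply(lst, min, numeric(1)))
  list(cells = lst[ord],
       mass = vapply(clusters, `[[`, numeric(1), "mass")[ord])
}
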