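# Imaginary coherence between channels and electrode clusters,
# baseline correction, and band/period aggregation.

#' Electrode cluster definition
#'
#' @param name Cluster name.
#' @param members Exactly 7 electrode labels.
#' @return A `cluster_def`.
#' @export
cluster_def <- function(name, members) {
  stopifnot(is.character(members), length(members) == 7L)
  structure(list(name = name, members = members), class = "cluster_def")
}

#' Default M1 electrode clusters
#'
#' Seven electrodes centred at C3 (left M1) and seven centred at C4 (right
#' M1). The C4 cluster includes C4 itself as its seventh member.
#' @return List of two `cluster_def`s named `C3` and `C4`.
#' @export
default_clusters <- function() {
  m <- sensorimotor_montage()
  list(C3 = cluster_def("C3", m$C3), C4 = cluster_def("C4", m$C4))
}

ch_index <- function(tfr, ch) {
  if (is.character(ch)) {
    i <- match(ch, tfr$channel_labels)
    if (is.na(i)) stop("unknown channel: ", ch, call. = FALSE)
    i
  } else as.integer(ch)
}

imcoh_from_spectra <- function(Sij, Sii, Sjj) {
  denom <- sqrt(Sii * Sjj)
  bad <- !(denom > 0)
  if (any(bad)) {
    warning(sprintf("%d (frequency, time) cells have zero auto-spectrum; emitted as NA",
                    sum(bad)), call. = FALSE)
    denom[bad] <- NA_real_
  }
  abs(Im(Sij / denom))
}

#' Across-trial imaginary coherence between two channels
#'
#' At every (frequency, time) cell, the cross-spectral density
#' `S_ij = mean_trials(x_i * Conj(x_j))` and auto-spectra `S_ii`, `S_jj`
#' (trial means of `|x|^2`) are formed from the complex wavelet values, and
#' the imaginary coherence `|Im(S_ij / sqrt(S_ii * S_jj))|` is returned.
#' Values lie in \[0, 1\]; 0 means no consistent non-zero-lag phase
#' relationship across trials.
#'
#' @param tfr An `eeg_tfr` with at least 2 trials.
#' @param i,j Channel labels or indices.
#' @return An `imcoh_map`: `values` (freqs x times), `freqs`, `times`,
#'   `estimator = "across"`, `n_trials`.
#' @export
imcoh_across_trials <- function(tfr, i, j) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  nt <- dim(tfr$values)[1L]
  if (nt < 2L) stop("across-trial ImCoh needs >= 2 trials", call. = FALSE)
  xi <- tfr$values[, ch_index(tfr, i), , , drop = FALSE]
  xj <- tfr$values[, ch_index(tfr, j), , , drop = FALSE]
  dim(xi) <- dim(xi)[c(1L, 3L, 4L)]; dim(xj) <- dim(xj)[c(1L, 3L, 4L)]
  Sij <- colMeans(xi * Conj(xj))
  Sii <- colMeans(Re(xi * Conj(xi)))
  Sjj <- colMeans(Re(xj * Conj(xj)))
  new_imcoh_map(imcoh_from_spectra(Sij, Sii, Sjj), tfr, "across", nt)
}

#' Within-trial imaginary coherence between two channels
#'
#' Per-trial connectivity: for each trial and frequency, the cross- and
#' auto-spectra are averaged over the grid points inside `window`
#' (half-open `[start, end)` in ms; `NULL` = the whole grid), and the
#' imaginary coherence is computed per trial. This is the trial-level
#' estimator feeding the long-format table (a single-time-point coherence is
#' identically 1, so trial-level values must aggregate over within-trial
#' time; windows with fewer than 2 grid points are rejected).
#'
#' @param tfr An `eeg_tfr`.
#' @param i,j Channel labels or indices.
#' @param window `c(start, end)` ms or `NULL` for the full grid.
#' @return Numeric matrix `trials x freqs` with attributes `freqs`, `window`.
#' @export
imcoh_within_trial <- function(tfr, i, j, window = NULL) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  tsel <- window_cols(tfr$times, window)
  if (length(tsel) < 2L) {
    stop("window must contain at least 2 grid points", call. = FALSE)
  }
  xi <- tfr$values[, ch_index(tfr, i), , tsel, drop = FALSE]
  xj <- tfr$values[, ch_index(tfr, j), , tsel, drop = FALSE]
  dim(xi) <- dim(xi)[c(1L, 3L, 4L)]; dim(xj) <- dim(xj)[c(1L, 3L, 4L)]
  Sij <- rowMeans(xi * Conj(xj), dims = 2L)
  Sii <- rowMeans(Re(xi * Conj(xi)), dims = 2L)
  Sjj <- rowMeans(Re(xj * Conj(xj)), dims = 2L)
  out <- imcoh_from_spectra(Sij, Sii, Sjj)
  attr(out, "freqs") <- tfr$freqs
  attr(out, "window") <- window
  out
}

# columns of the time grid inside a half-open [start, end) window;
# window = NULL selects everything.
window_cols <- function(times, window) {
  if (is.null(window)) return(seq_along(times))
  which(times >= window[1L] & times < window[2L])
}

#' Cluster-to-cluster imaginary coherence
#'
#' Arithmetic mean of the pairwise estimates over all 49 (i in A, j in B)
#' electrode pairs, using either the across-trial or the within-trial
#' estimator.
#'
#' @param tfr An `eeg_tfr` containing all member channels.
#' @param A,B Disjoint [cluster_def()]s.
#' @param estimator `"across"` or `"within"`.
#' @param window Within-trial estimator: time window in ms (see
#'   [imcoh_within_trial()]).
#' @return An `imcoh_map` (`estimator = "across"`) or a trials x freqs
#'   matrix (`"within"`).
#' @export
cluster_imcoh <- function(tfr, A = default_clusters()$C3,
                          B = default_clusters()$C4,
                          estimator = c("across", "within"), window = NULL) {
  stopifnot(inherits(A, "cluster_def"), inherits(B, "cluster_def"))
  estimator <- match.arg(estimator)
  if (length(intersect(A$members, B$members)) > 0L) {
    stop("clusters overlap: ",
         paste(intersect(A$members, B$members), collapse = ", "),
         call. = FALSE)
  }
  acc <- NULL
  for (i in A$members) for (j in B$members) {
    v <- if (estimator == "across") imcoh_across_trials(tfr, i, j)$values
         else imcoh_within_trial(tfr, i, j, window)
    acc <- if (is.null(acc)) v else acc + v
  }
  avg <- acc / (length(A$members) * length(B$members))
  if (estimator == "across") {
    new_imcoh_map(avg, tfr, "across", dim(tfr$values)[1L],
                  pair = paste(A$name, B$name, sep = "-"))
  } else {
    attr(avg, "freqs") <- tfr$freqs
    attr(avg, "window") <- window
    avg
  }
}

new_imcoh_map <- function(values, tfr, estimator, n_trials, pair = NULL,
                          baseline = NULL) {
  structure(list(values = values, freqs = tfr$freqs, times = tfr$times,
                 estimator = estimator, n_trials = n_trials, pair = pair,
                 baseline = baseline),
            class = "imcoh_map")
}

#' Baseline-correct an event-related ImCoh map
#'
#' Subtracts, per frequency, the mean ImCoh over the baseline window from
#' every time point. The map's grid must cover the baseline window (the
#' event pipeline computes its maps on the combined
#' `tfr_grid("event_full")`). Output values may be negative.
#'
#' @param map An `imcoh_map`.
#' @param baseline `c(start, end)` ms, inclusive of grid points at both
#'   edges. Default `c(-2000, -1000)`.
#' @return The baseline-subtracted `imcoh_map` (with `baseline` recorded).
#' @export
baseline_subtract <- function(map, baseline = c(-2000, -1000)) {
  stopifnot(inherits(map, "imcoh_map"))
  cols <- which(map$times >= baseline[1L] & map$times <= baseline[2L])
  if (length(cols) == 0L) {
    stop("map grid does not cover the baseline window", call. = FALSE)
  }
  bl <- rowMeans(map$values[, cols, drop = FALSE], na.rm = TRUE)
  map$values <- map$values - bl
  map$baseline <- baseline
  map
}

#' Restrict an ImCoh map to a time window
#'
#' @param map An `imcoh_map`.
#' @param window `c(start, end)` ms; grid points with
#'   `start <= t <= end` are kept.
#' @return The restricted `imcoh_map`.
#' @export
crop_map <- function(map, window) {
  cols <- which(map$times >= window[1L] & map$times <= window[2L])
  map$values <- map$values[, cols, drop = FALSE]
  map$times <- map$times[cols]
  map
}

#' Frequency bands and movement periods
#'
#' Band edges in Hz (inclusive at both ends) and period windows in ms.
#' Time windows are half-open `[start, end)`; the `resting` period denotes
#' the full resting analysis grid.
#' @return Named lists of `c(lo, hi)` pairs.
#' @export
imcoh_bands <- function() {
  list(theta = c(4, 7), alpha = c(8, 12), beta = c(13, 30), gamma = c(60, 90))
}

#' @rdname imcoh_bands
#' @export
imcoh_periods <- function() {
  list(resting = c(400, 1620), premove = c(-500, 0), move = c(0, 500),
       postmove = c(1500, 4000))
}

#' Average ImCoh over a frequency band and time period
#'
#' For an `imcoh_map`, returns the scalar mean over the band's frequency
#' bins (inclusive edges) and the period's grid points (half-open window).
#' For a trials x freqs matrix from the within-trial estimator (already
#' period-resolved), returns the per-trial band mean. Missing cells are
#' excluded from the mean.
#'
#' @param x An `imcoh_map` or a within-trial trials x freqs matrix.
#' @param band Band name in [imcoh_bands()] or a `c(lo, hi)` pair in Hz.
#' @param period Period name in [imcoh_periods()] or a `c(start, end)` pair
#'   in ms (maps only).
#' @return Scalar (map) or numeric vector of per-trial values (matrix).
#' @export
band_period_average <- function(x, band, period = NULL) {
  if (is.character(band)) {
    band <- imcoh_bands()[[match.arg(band, names(imcoh_bands()))]]
  }
  if (inherits(x, "imcoh_map")) {
    if (is.character(period)) {
      period <- imcoh_periods()[[match.arg(period, names(imcoh_periods()))]]
    }
    rows <- which(x$freqs >= band[1L] & x$freqs <= band[2L])
    cols <- if (is.null(period)) seq_along(x$times) else
      window_cols(x$times, period)
    if (length(rows) == 0L || length(cols) == 0L) {
      stop("band or period selects no cells", call. = FALSE)
    }
    mean(x$values[rows, cols], na.rm = TRUE)
  } else {
    freqs <- attr(x, "freqs")
    if (is.null(freqs)) stop("matrix input must carry a `freqs` attribute",
                             call. = FALSE)
    rows <- which(freqs >= band[1L] & freqs <= band[2L])
    if (length(rows) == 0L) stop("band selects no frequency bins",
                                 call. = FALSE)
    rowMeans(x[, rows, drop = FALSE], na.rm = TRUE)
  }
}

#' Percent change between two connectivity values
#'
#' `100 * (b - a) / |a|`, elementwise. Cells where `|a|` does not exceed
#' `eps` (default `1e-6` of the dynamic range of `a`) are returned as `NA`
#' with a warning rather than silently exploding.
#'
#' @param a,b Numeric scalars, vectors or matrices of equal shape (`a` the
#'   earlier block, `b` the later).
#' @param eps Denominator guard; default `1e-6 * max(|a|)`.
#' @return Percent change, same shape as the inputs.
#' @export
percent_change <- function(a, b, eps = NULL) {
  stopifnot(length(a) == length(b))
  if (is.null(eps)) eps <- 1e-6 * max(abs(a), na.rm = TRUE)
  out <- 100 * (b - a) / abs(a)
  und <- !is.na(a) & abs(a) <= eps
  if (any(und)) {
    warning(sprintf("%d cell(s) have |baseline| <= eps; percent change undefined (NA)",
                    sum(und)), call. = FALSE)
    out[und] <- NA_real_
  }
  out
}

#' @export
print.imcoh_map <- function(x, ...) {
  cat(sprintf("<imcoh_map> %s-trial estimator, %d freqs x %d times, %d trials\n",
              x$estimator, nrow(x$values), ncol(x$values), x$n_trials))
  if (!is.null(x$pair)) cat("  cluster pair:", x$pair, "\n")
  if (!is.null(x$baseline)) {
    cat(sprintf("  baseline-subtracted (%g to %g ms)\n",
                x$baseline[1L], x$baseline[2L]))
  }
  cat(sprintf("  value range [%.4f, %.4f]\n", min(x$values, na.rm = TRUE),
              max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.imcoh_map <- function(x, ...) {
  graphics::image(x$times, x$freqs, t(x$values),
                  xlab = "time (ms)", ylab = "frequency (Hz)",
                  main = sprintf("ImCoh (%s-trial)", x$estimator),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
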