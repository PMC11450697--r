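#' Oscillator source parameters
#'
#' Parameters of the pair of phase-coupled sinusoidal sources that drive the
#' two sensorimotor electrode clusters in the synthetic recordings. The
#' inter-cluster phase lag of each trial is drawn from a von Mises
#' distribution with mean `phi` and concentration `kappa`; the consistency of
#' that lag across trials is exactly what imaginary coherence measures, so
#' these two numbers fix the ground-truth connectivity (see
#' [expected_imcoh()]).
#'
#' @param f0 Carrier frequency in Hz. Default 20 (the beta stimulation
#'   frequency).
#' @param phi Mean inter-cluster phase lag in radians, in (-pi, pi]. Default
#'   `pi/2`: a quadrature lag, maximally visible to the imaginary part of
#'   coherency.
#' @param kappa Von Mises concentration of trial-to-trial phase-lag jitter
#'   (dimensionless, >= 0). `Inf` means no jitter; 0 means a uniformly random
#'   lag each trial (no consistent coupling). Default 4.
#' @param amp Source peak amplitude in microvolts. Default 10.
#' @return An object of class `oscillator_params`.
#' @export
oscillator_params <- function(f0 = 20, phi = pi / 2, kappa = 4, amp = 10) {
  stopifnot(is.numeric(f0), length(f0) == 1L, f0 > 0)
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi)) {
    stop("`phi` must be a finite number in (-pi, pi]", call. = FALSE)
  }
  if (phi <= -pi || phi > pi) stop("`phi` must lie in (-pi, pi]", call. = FALSE)
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa >= 0)
  stopifnot(is.numeric(amp), length(amp) == 1L, amp >= 0)
  structure(list(f0 = f0, phi = phi, kappa = kappa, amp = amp),
            class = "oscillator_params")
}

#' Movement-locked beta amplitude envelope
#'
#' Relative amplitude of the beta sources across an event-related trial,
#' emulating the canonical movement triad: pre-movement event-related
#' desynchronization (ERD), movement ERD, and post-movement event-related
#' synchronization (ERS, the beta rebound). Gains are multiplicative relative
#' to `baseline_gain`; level changes are smoothed with half-cosine ramps of
#' width `transition_ms` centred between the analysis windows.
#'
#' @param baseline_gain Relative amplitude during the baseline window
#'   (-2000 to -1000 ms). Default 1.
#' @param premove_gain Relative amplitude in the pre-movement window
#'   (-500 to 0 ms). Default 0.6 (ERD).
#' @param move_gain Relative amplitude in the movement window (0 to 500 ms).
#'   Default 0.4 (deeper ERD).
#' @param rebound_gain Relative amplitude in the post-movement window
#'   (1500 to 4000 ms). Default 1.5 (ERS).
#' @param transition_ms Half-cosine smoothing width in ms. Default 250.
#' @return An object of class `erd_profile`.
#' @export
erd_profile <- function(baseline_gain = 1, premove_gain = 0.6,
                        move_gain = 0.4, rebound_gain = 1.5,
                        transition_ms = 250) {
  gains <- c(baseline_gain, premove_gain, move_gain, rebound_gain)
  stopifnot(all(is.finite(gains)), all(gains >= 0), transition_ms >= 0)
  structure(list(baseline_gain = baseline_gain, premove_gain = premove_gain,
                 move_gain = move_gain, rebound_gain = rebound_gain,
                 transition_ms = transition_ms),
            class = "erd_profile")
}

#' Source-to-sensor mixing model
#'
#' How the two cluster sources project to the 14 scalp channels.
#' `leakage` mixes each source into the opposite cluster with zero lag,
#' emulating volume conduction -- the confound imaginary coherence is chosen
#' to resist (at `leakage = 1` the two clusters see identical zero-lag
#' mixtures and the true ImCoh is 0).
#'
#' @param gains_A,gains_B Per-channel gains for the 7 channels of each
#'   cluster. Defaults `rep(1, 7)`.
#' @param leakage Zero-lag cross-cluster mixing coefficient in \[0, 1\].
#'   Default 0.
#' @param noise_exponent Spectral slope beta of the 1/f^beta background
#'   noise. Default 1.
#' @param snr Ratio of source peak amplitude to background-noise RMS (> 0).
#'   Default 1.
#' @return An object of class `mixing_model`.
#' @export
mixing_model <- function(gains_A = rep(1, 7), gains_B = rep(1, 7),
                         leakage = 0, noise_exponent = 1, snr = 1) {
  stopifnot(length(gains_A) == 7L, length(gains_B) == 7L,
            all(is.finite(gains_A)), all(is.finite(gains_B)))
  stopifnot(is.numeric(leakage), length(leakage) == 1L,
            leakage >= 0, leakage <= 1)
  stopifnot(is.numeric(snr), length(snr) == 1L, snr > 0)
  structure(list(gains_A = as.numeric(gains_A), gains_B = as.numeric(gains_B),
                 leakage = leakage, noise_exponent = noise_exponent,
                 snr = snr),
            class = "mixing_model")
}

#' Electrode labels of the two sensorimotor clusters
#'
#' Seven channels centred at C3 (left M1) and seven centred at C4 (right
#' M1), following the 10-20 nomenclature.
#' @return Named list with character vectors `C3` and `C4`.
#' @export
sensorimotor_montage <- function() {
  list(C3 = c("C3", "FC3", "C1", "FC5", "CP1", "C5", "CP3"),
       C4 = c("C4", "CP2", "CP4", "C6", "C2", "FC6", "FC4"))
}

#' Expected imaginary coherence of the generative model
#'
#' Closed-form across-trial expectation of the imaginary-coherence estimator
#' for two noise-free constant-amplitude sinusoids whose per-trial phase lag
#' is von Mises distributed: `|sin(phi)| * R(kappa)`, where
#' `R(kappa) = I1(kappa) / I0(kappa)` is the mean resultant length of the von
#' Mises distribution (ratio of modified Bessel functions). `R(Inf) = 1`
#' (perfectly consistent lag), `R(0) = 0` (uniform lag).
#'
#' @param phi Mean phase lag in radians (finite).
#' @param kappa Concentration (>= 0, `Inf` allowed). Vectorized over both.
#' @return Expected ImCoh in \[0, 1\].
#' @examples
#' expected_imcoh(pi / 2, Inf)  # 1
#' expected_imcoh(0, 5)         # 0: zero lag has no imaginary part
#' @export
expected_imcoh <- function(phi, kappa) {
  if (any(!is.finite(phi))) stop("`phi` must be finite", call. = FALSE)
  if (any(kappa < 0)) stop("`kappa` must be >= 0", call. = FALSE)
  n <- max(length(phi), length(kappa))
  phi <- rep_len(phi, n); kappa <- rep_len(kappa, n)
  r <- ifelse(is.infinite(kappa), 1,
              ifelse(kappa == 0, 0,
                     besselI(pmin(kappa, 1e6), 1, expon.scaled = TRUE) /
                       besselI(pmin(kappa, 1e6), 0, expon.scaled = TRUE)))
  abs(sin(phi)) * r
}

# Von Mises sampler (Best & Fisher 1979 wrapped-Cauchy rejection).
# kappa = 0 -> uniform; kappa = Inf -> point mass at mu.
rvonmises <- function(n, mu, kappa) {
  if (is.infinite(kappa)) return(rep(mu, n))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  th <- out + mu
  atan2(sin(th), cos(th))
}

# Gaussian noise with a 1/f^beta amplitude spectrum, unit RMS.
onef_noise <- function(n, beta) {
  w <- stats::rnorm(n)
  if (beta == 0) return(w / stats::sd(w))
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)               # two-sided frequency index
  s <- c(0, f[-1]^(-beta / 2))      # kill DC, shape the rest
  x <- Re(stats::fft(X * s, inverse = TRUE) / n)
  x / stats::sd(x)
}

#' Generate one continuous synthetic EEG recording
#'
#' Builds a 1000 Hz multichannel recording in which two 7-channel clusters
#' (centred at C3 and C4) are driven by phase-lagged sinusoidal sources on a
#' 1/f noise floor. In `resting` mode the recording is a sequence of
#' `n_trials` two-second segments, each with its own random carrier phase and
#' a phase lag drawn von Mises(`phi`, `kappa * kappa_scale`); amplitude is
#' constant within each segment. In `event` mode, `n_trials` self-paced
#' movements occur at `spacing_s` intervals; the beta sources are amplitude
#' modulated by the ERD/ERS envelope around each movement onset, and a force
#' channel carries one half-cosine pulse (200 ms rise) per movement starting
#' exactly at the listed onset.
#'
#' Identical `(seed, params)` give bit-identical output.
#'
#' @param mode `"resting"` or `"event"`.
#' @param osc [oscillator_params()].
#' @param mix [mixing_model()].
#' @param erd [erd_profile()] (required in event mode).
#' @param n_trials Number of 2 s resting segments (default 90, i.e. 3 min) or
#'   number of movements (default 60).
#' @param spacing_s Event mode: movement spacing in seconds. Default 10.
#' @param kappa_scale Multiplier applied to `osc$kappa` (the study-design
#'   effect map enters here). Default 1.
#' @param seed Integer seed; required for reproducibility.
#' @param meta Named list of trial metadata (participant, intensity,
#'   timepoint, ...) carried through the pipeline.
#' @return An `eeg_recording`: list with `data` (channels x samples matrix,
#'   microvolts), `rate` (Hz), `channel_labels`, `force` (numeric vector or
#'   NULL), `onsets` (seconds, event mode), `meta`, and the drawn per-trial
#'   phase lags in `truth`.
#' @export
generate_recording <- function(mode = c("resting", "event"),
                               osc = oscillator_params(),
                               mix = mixing_model(),
                               erd = erd_profile(),
                               n_trials = NULL,
                               spacing_s = 10,
                               kappa_scale = 1,
                               seed = NULL,
                               meta = list()) {
  mode <- match.arg(mode)
  stopifnot(inherits(osc, "oscillator_params"), inherits(mix, "mixing_model"))
  if (mode == "event" && !inherits(erd, "erd_profile")) {
    stop("event mode requires an `erd_profile`", call. = FALSE)
  }
  if (is.null(seed)) stop("`seed` is required for a reproducible recording",
                          call. = FALSE)
  if (is.null(n_trials)) n_trials <- if (mode == "resting") 90L else 60L
  stopifnot(n_trials >= 1L)
  rate <- 1000L
  kappa_eff <- osc$kappa * kappa_scale

  montage <- sensorimotor_montage()
  labels <- c(montage$C3, montage$C4)
  nch <- length(labels)

  with_seed(seed, {
    if (mode == "resting") {
      seg_len <- 2L * rate
      n <- n_trials * seg_len
      t_seg <- (seq_len(seg_len) - 1L) / rate
      lags <- rvonmises(n_trials, osc$phi, kappa_eff)
      theta0 <- stats::runif(n_trials, -pi, pi)
      src_a <- numeric(n); src_b <- numeric(n)
      for (k in seq_len(n_trials)) {
        idx <- (k - 1L) * seg_len + seq_len(seg_len)
        ph <- 2 * pi * osc$f0 * t_seg + theta0[k]
        src_a[idx] <- osc$amp * cos(ph)
        src_b[idx] <- osc$amp * cos(ph + lags[k])
      }
      force <- NULL; onsets <- NULL
    } else {
      lead <- 5  # seconds before first onset
      n <- as.integer(round((lead + n_trials * spacing_s) * rate))
      onsets <- lead + (seq_len(n_trials) - 1L) * spacing_s
      lags <- rvonmises(n_trials, osc$phi, kappa_eff)
      theta0 <- stats::runif(n_trials, -pi, pi)
      tt <- (seq_len(n) - 1L) / rate
      src_a <- numeric(n); src_b <- numeric(n)
      env <- erd_envelope(erd)
      for (k in seq_len(n_trials)) {
        i0 <- as.integer(round((onsets[k] - spacing_s / 2) * rate)) + 1L
        i1 <- min(n, as.integer(round((onsets[k] + spacing_s / 2) * rate)))
        i0 <- max(1L, i0)
        idx <- i0:i1
        trel <- (tt[idx] - onsets[k]) * 1000  # ms relative to onset
        g <- env(trel)
        ph <- 2 * pi * osc$f0 * (tt[idx] - onsets[k]) + theta0[k]
        src_a[idx] <- osc$amp * g * cos(ph)
        src_b[idx] <- osc$amp * g * cos(ph + lags[k])
      }
      force <- force_trace(n, rate, onsets)
    }

    mixed_a <- src_a + mix$leakage * src_b
    mixed_b <- src_b + mix$leakage * src_a
    noise_rms <- osc$amp / mix$snr
    data <- matrix(0, nrow = nch, ncol = n)
    for (k in 1:7) {
      data[k, ] <- mix$gains_A[k] * mixed_a +
        noise_rms * onef_noise(n, mix$noise_exponent)
    }
    for (k in 1:7) {
      data[7L + k, ] <- mix$gains_B[k] * mixed_b +
        noise_rms * onef_noise(n, mix$noise_exponent)
    }
    rownames(data) <- labels

    structure(list(data = data, rate = rate, channel_labels = labels,
                   force = force, onsets = onsets, meta = meta,
                   truth = list(mode = mode, phi = osc$phi,
                                kappa = kappa_eff, f0 = osc$f0,
                                lags = lags,
                                expected_imcoh = expected_imcoh(osc$phi,
                                                                kappa_eff)),
                   seed = seed),
              class = "eeg_recording")
  })
}

# Piecewise amplitude envelope with half-cosine transitions. Level changes
# are centred at -750 ms (baseline -> premove), 0 ms (premove -> move),
# 1000 ms (move -> rebound) and 4250 ms (rebound -> baseline).
erd_envelope <- function(erd) {
  centers <- c(-750, 0, 1000, 4250)
  levels <- c(erd$baseline_gain, erd$premove_gain, erd$move_gain,
              erd$rebound_gain, erd$baseline_gain)
  w <- erd$transition_ms
  function(t_ms) {
    g <- rep(levels[1L], length(t_ms))
    for (s in seq_along(centers)) {
      lo <- centers[s] - w / 2; hi <- centers[s] + w / 2
      ramp <- levels[s] + (levels[s + 1L] - levels[s]) *
        0.5 * (1 - cos(pi * pmin(pmax((t_ms - lo) / max(w, 1e-9), 0), 1)))
      g <- ifelse(t_ms >= hi, levels[s + 1L], ifelse(t_ms > lo, ramp, g))
    }
    g
  }
}

# One half-cosine force pulse per onset: 200 ms rise to 1 N, 400 ms plateau,
# 400 ms half-cosine release. Zero baseline.
force_trace <- function(n, rate, onsets) {
  rise <- 0.2; hold <- 0.4; fall <- 0.4
  force <- numeric(n)
  tt <- (seq_len(n) - 1L) / rate
  for (on in onsets) {
    idx <- which(tt >= on & tt < on + rise + hold + fall)
    tr <- tt[idx] - on
    v <- ifelse(tr < rise, 0.5 * (1 - cos(pi * tr / rise)),
                ifelse(tr < rise + hold, 1,
                       0.5 * (1 + cos(pi * (tr - rise - hold) / fall))))
    force[idx] <- pmax(force[idx], v)
  }
  force
}

#' Study design for a synthetic tACS experiment
#'
#' Crossed design: every participant is recorded at every stimulation
#' intensity and time point, once resting and once event-related. The
#' `effect_map` multiplies the phase-jitter concentration `kappa` per
#' (intensity, timepoint) cell, standing in for stimulation after-effects on
#' coupling consistency; sham and all pre-stimulation cells default to 1
#' (no change). The defaults emulate the qualitative pattern of a delayed
#' increase at the lowest intensity and suppression at the higher ones; they
#' are free parameters of the simulation, not estimates.
#'
#' @param n_participants Number of participants (>= 1).
#' @param intensities Stimulation labels. Default
#'   `c("sham", "0.5mA", "1.0mA", "1.5mA")`.
#' @param timepoints Recording block labels. Default
#'   `c("pre", "post1", "post2")`.
#' @param trials_resting Resting 2 s epochs per block. Default 90 (3 min).
#' @param trials_event Movements per block. Default 60.
#' @param effect_map Numeric matrix `intensities x timepoints` of
#'   multiplicative kappa changes; must cover every cell.
#' @param seed Master seed; all per-recording seeds derive from it.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_participants = 2L,
                         intensities = c("sham", "0.5mA", "1.0mA", "1.5mA"),
                         timepoints = c("pre", "post1", "post2"),
                         trials_resting = 90L,
                         trials_event = 60L,
                         effect_map = NULL,
                         seed = 1L) {
  stopifnot(n_participants >= 1L, trials_resting >= 1L, trials_event >= 1L)
  if (is.null(effect_map)) {
    effect_map <- matrix(1, length(intensities), length(timepoints),
                         dimnames = list(intensities, timepoints))
    set_cell <- function(i, t, v) {
      if (i %in% intensities && t %in% timepoints) effect_map[i, t] <<- v
    }
    set_cell("0.5mA", "post2", 1.6)
    set_cell("1.0mA", "post1", 0.5); set_cell("1.0mA", "post2", 0.8)
    set_cell("1.5mA", "post1", 0.9); set_cell("1.5mA", "post2", 0.6)
  }
  if (!all(intensities %in% rownames(effect_map)) ||
      !all(timepoints %in% colnames(effect_map))) {
    stop("`effect_map` must have a row per intensity and a column per timepoint",
         call. = FALSE)
  }
  if (any(!is.finite(effect_map[intensities, timepoints]))) {
    stop("`effect_map` is missing a cell", call. = FALSE)
  }
  structure(list(n_participants = as.integer(n_participants),
                 intensities = intensities, timepoints = timepoints,
                 trials_resting = as.integer(trials_resting),
                 trials_event = as.integer(trials_event),
                 effect_map = effect_map, seed = as.integer(seed)),
            class = "study_design")
}

#' Generate a full synthetic study
#'
#' One resting and one event recording per (participant, intensity,
#' timepoint) cell, plus a ground-truth manifest recording the effective
#' kappa, phi and expected ImCoh of every recording for later recovery
#' checks. A pure function of the design (which includes the master seed):
#' repeated calls are identical.
#'
#' @param design A [study_design()].
#' @param osc,mix,erd Generator parameters shared by all cells.
#' @param materialize If `FALSE`, return only the manifest plus a `realize`
#'   function that generates any single recording on demand (memory-friendly
#'   for large designs).
#' @return List with `manifest` (data.frame) and either `recordings` (named
#'   list of `eeg_recording`) or `realize(row)` closure.
#' @export
generate_study <- function(design, osc = oscillator_params(),
                           mix = mixing_model(), erd = erd_profile(),
                           materialize = TRUE) {
  stopifnot(inherits(design, "study_design"))
  cells <- expand.grid(participant = seq_len(design$n_participants),
                       intensity = design$intensities,
                       timepoint = design$timepoints,
                       mode = c("resting", "event"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[order(cells$participant, cells$intensity, cells$timepoint,
                       cells$mode), , drop = FALSE]
  rownames(cells) <- NULL
  scale <- design$effect_map[cbind(cells$intensity, cells$timepoint)]
  cells$kappa_scale <- scale
  cells$kappa_eff <- osc$kappa * scale
  cells$phi <- osc$phi
  cells$expected_imcoh <- expected_imcoh(osc$phi, cells$kappa_eff)
  cells$seed <- (design$seed + 7919L * seq_len(nrow(cells))) %% 2147483647L
  cells$id <- sprintf("p%02d_%s_%s_%s", cells$participant, cells$intensity,
                      cells$timepoint, cells$mode)

  realize <- function(row) {
    cell <- cells[row, ]
    generate_recording(
      mode = cell$mode, osc = osc, mix = mix, erd = erd,
      n_trials = if (cell$mode == "resting") design$trials_resting
                 else design$trials_event,
      kappa_scale = cell$kappa_scale, seed = cell$seed,
      meta = list(participant = cell$participant, intensity = cell$intensity,
                  timepoint = cell$timepoint))
  }
  out <- list(manifest = cells, realize = realize)
  if (materialize) {
    out$recordings <- stats::setNames(lapply(seq_len(nrow(cells)), realize),
                                      cells$id)
  }
  class(out) <- "imcoh_study"
  out
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %d Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  if (!is.null(x$onsets)) {
    cat(sprintf("  %d movement onsets, force channel present\n",
                length(x$onsets)))
  }
  invisible(x)
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "<study_design> %d participants x %d intensities x %d timepoints\n",
    x$n_participants, length(x$intensities), length(x$timepoints)))
  cat(sprintf("  %d resting epochs + %d movements per block; master seed %d\n",
              x$trials_resting, x$trials_event, x$seed))
  invisible(x)
}
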