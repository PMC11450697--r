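# Constructed-signal identities and properties of the ImCoh estimators.

# helper: tfr with unit-modulus values and per-trial phases th (ch1) and
# th + lag (ch2), constant over a small freq x time grid
two_channel_tfr <- function(lags, nf = 3, ntime = 4) {
  nt <- length(lags)
  vals <- array(0i, c(nt, 2, nf, ntime))
  th <- seq(0, 2 * pi, length.out = nt + 1)[seq_len(nt)]
  for (k in seq_len(nt)) {
    vals[k, 1, , ] <- exp(1i * th[k])
    vals[k, 2, , ] <- exp(1i * (th[k] - lags[k]))
  }
  make_tfr(vals, freqs = seq_len(nf), times = seq_len(ntime) * 20,
           labels = c("a", "b"))
}

test_that("self-coherence is zero and quadrature lag gives one", {
  tfr <- two_channel_tfr(rep(pi / 2, 8))
  self <- imcoh_across_trials(tfr, "a", "a")
  expect_true(all(self$values < 1e-12))
  pair <- imcoh_across_trials(tfr, "a", "b")
  expect_equal(unname(pair$values), matrix(1, 3, 4), tolerance = 1e-12)
  # within-trial estimator agrees on both identities
  w_self <- imcoh_within_trial(tfr, "a", "a")
  expect_true(all(w_self < 1e-12))
  w_pair <- imcoh_within_trial(tfr, "a", "b")
  expect_equal(matrix(w_pair, 8, 3), matrix(1, 8, 3), tolerance = 1e-12)
})

test_that("estimator is symmetric in its channels and bounded in [0, 1]", {
  set.seed(21)
  vals <- array(complex(real = rnorm(6 * 2 * 4 * 5),
                        imaginary = rnorm(6 * 2 * 4 * 5)),
                c(6, 2, 4, 5))
  tfr <- make_tfr(vals, freqs = 1:4, times = (1:5) * 20)
  ij <- imcoh_across_trials(tfr, 1, 2)
  ji <- imcoh_across_trials(tfr, 2, 1)
  expect_equal(ij$values, ji$values, tolerance = 1e-12)
  expect_true(all(ij$values >= 0 & ij$values <= 1))
  wij <- imcoh_within_trial(tfr, 1, 2)
  expect_equal(wij, imcoh_within_trial(tfr, 2, 1), tolerance = 1e-12)
  expect_true(all(wij >= 0 & wij <= 1))
})

test_that("ImCoh is invariant to positive per-channel rescaling", {
  set.seed(22)
  vals <- array(complex(real = rnorm(5 * 2 * 3 * 4),
                        imaginary = rnorm(5 * 2 * 3 * 4)), c(5, 2, 3, 4))
  tfr <- make_tfr(vals, freqs = 1:3, times = (1:4) * 20)
  base <- imcoh_across_trials(tfr, 1, 2)$values
  tfr$values[, 1, , ] <- 7.3 * tfr$values[, 1, , ]
  tfr$values[, 2, , ] <- 0.01 * tfr$values[, 2, , ]
  expect_equal(imcoh_across_trials(tfr, 1, 2)$values, base,
               tolerance = 1e-12)
})

test_that("across-trial estimate needs >= 2 trials; within needs >= 2 grid points", {
  tfr <- two_channel_tfr(pi / 2)
  expect_error(imcoh_across_trials(tfr, "a", "b"), ">= 2 trials")
  tfr8 <- two_channel_tfr(rep(pi / 2, 8))
  expect_error(imcoh_within_trial(tfr8, "a", "b", window = c(20, 40)),
               "2 grid points")
})

test_that("zero auto-spectrum cells propagate as NA with a warning", {
  tfr <- two_channel_tfr(rep(pi / 2, 4))
  tfr$values[, 2, 2, ] <- 0
  expect_warning(m <- imcoh_across_trials(tfr, "a", "b"), "zero auto")
  expect_true(all(is.na(m$values[2, ])))
  expect_true(all(!is.na(m$values[-2, ])))
})

test_that("cluster averaging equals the mean of pairwise maps", {
  set.seed(23)
  labs <- unlist(sensorimotor_montage(), use.names = FALSE)
  vals <- array(complex(real = rnorm(4 * 14 * 2 * 3),
                        imaginary = rnorm(4 * 14 * 2 * 3)), c(4, 14, 2, 3))
  tfr <- make_tfr(vals, freqs = 1:2, times = (1:3) * 20, labels = labs)
  cl <- default_clusters()
  got <- cluster_imcoh(tfr, cl$C3, cl$C4, "across")
  acc <- 0
  for (i in cl$C3$members) for (j in cl$C4$members) {
    acc <- acc + imcoh_across_trials(tfr, i, j)$values
  }
  expect_equal(got$values, acc / 49, tolerance = 1e-12)
  # symmetry under swapping the clusters
  swapped <- cluster_imcoh(tfr, cl$C4, cl$C3, "across")
  expect_equal(swapped$values, got$values, tolerance = 1e-12)
  # identical pairs: mean equals any single pair
  vals2 <- vals
  for (c in 2:14) vals2[, c, , ] <- vals2[, 1, , ]
  # make cluster B distinct from A but identical within each cluster
  vals2[, 8:14, , ] <- vals2[, 8:14, , ] * exp(1i * pi / 3)
  tfr2 <- make_tfr(vals2, freqs = 1:2, times = (1:3) * 20, labels = labs)
  got2 <- cluster_imcoh(tfr2, cl$C3, cl$C4, "across")
  expect_equal(got2$values, imcoh_across_trials(tfr2, "C3", "C4")$values,
               tolerance = 1e-12)
  # overlapping clusters are rejected
  expect_error(cluster_imcoh(tfr, cl$C3, cl$C3, "across"), "overlap")
})

test_that("volume-conducted (zero-lag) mixtures show near-zero ImCoh", {
  # leakage = 1: both clusters receive the identical zero-lag source mixture
  rec <- generate_recording("resting",
                            osc = oscillator_params(phi = pi / 2, kappa = 4),
                            mix = mixing_model(leakage = 1, snr = 1),
                            n_trials = 150, seed = 31)
  ep <- epoch_recording(rec, "resting")
  tfr <- tfr_transform(select_channels(ep, c("C3", "C4")),
                       build_wavelet_bank(18, 22, 1, 5, 5),
                       tfr_grid("resting"))
  m <- imcoh_across_trials(tfr, "C3", "C4")
  expect_lt(mean(m$values[3, ]), 0.1)
})

test_that("baseline subtraction removes the per-frequency baseline mean", {
  times <- seq(-2000, 4000, 20)
  vals <- matrix(0.3, nrow = 4, ncol = length(times))
  map <- structure(list(values = vals, freqs = 13:16, times = times,
                        estimator = "across", n_trials = 10, pair = NULL,
                        baseline = NULL), class = "imcoh_map")
  # constant-in-time map -> 0 everywhere
  b <- baseline_subtract(map)
  expect_true(all(abs(b$values) < 1e-12))
  # +0.1 offset in the movement window survives untouched
  map2 <- map
  mv <- map2$times >= 0 & map2$times < 500
  map2$values[, mv] <- map2$values[, mv] + 0.1
  b2 <- baseline_subtract(map2)
  expect_equal(unname(b2$values[, mv]), matrix(0.1, 4, sum(mv)))
  expect_true(all(abs(b2$values[, !mv]) < 1e-12))
  # idempotent once the baseline mean is zero
  b3 <- baseline_subtract(b2)
  expect_equal(b3$values, b2$values)
  # window not covered -> error
  map$times <- seq(0, 500, 20)[seq_len(ncol(map$values))]
  expect_error(baseline_subtract(map), "baseline window")
})

test_that("band/period averaging and percent change follow their contracts", {
  times <- seq(-2000, 4000, 20)
  vals <- matrix(0.25, nrow = 87, ncol = length(times))
  map <- structure(list(values = vals, freqs = 4:90, times = times,
                        estimator = "across", n_trials = 10, pair = NULL,
                        baseline = NULL), class = "imcoh_map")
  expect_equal(band_period_average(map, "beta", "move"), 0.25)
  # beta band spans the 18 one-Hz bins from 13 to 30 inclusive
  expect_length(which(map$freqs >= 13 & map$freqs <= 30), 18)
  # trial-matrix route: uniform rows average to themselves
  tm <- matrix(0.4, nrow = 3, ncol = 87)
  attr(tm, "freqs") <- 4:90
  expect_equal(band_period_average(tm, "gamma"), rep(0.4, 3))
  expect_equal(percent_change(0.10, 0.12), 20)
  expect_equal(percent_change(-0.10, -0.08), 20)
  expect_warning(out <- percent_change(c(0, 0.1), c(0.05, 0.2)), "undefined")
  expect_true(is.na(out[1]) && !is.na(out[2]))
})
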