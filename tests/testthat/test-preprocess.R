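rms <- function(x) sqrt(mean(x^2))

test_that("band-pass + notch meets its attenuation and passband contracts", {
  tt <- (0:59999) / 1000
  mid <- 20000:40000  # steady-state region, clear of filter edges
  ratio <- function(f_hz) {
    rec <- make_recording(matrix(sin(2 * pi * f_hz * tt), 1))
    out <- bandpass_notch(rec)
    rms(out$data[1, mid]) / rms(rec$data[1, mid])
  }
  expect_lt(ratio(50), 0.01)            # notch: >= 40 dB at 50 Hz
  expect_equal(ratio(20), 1, tolerance = 0.05)
  # passband ripple < 1 dB between 1 and 90 Hz
  for (f in c(1, 5, 45, 55, 90)) {
    expect_gt(ratio(f), 10^(-1 / 20))
    expect_lt(ratio(f), 10^(1 / 20))
  }
  # DC is below the 0.5 Hz edge
  rec <- make_recording(matrix(1, 1, 60000))
  out <- bandpass_notch(rec)
  expect_lt(max(abs(out$data[1, mid])), 0.01)
  # rate precondition
  expect_error(bandpass_notch(make_recording(matrix(0, 1, 1000), rate = 150)),
               "too low")
})

test_that("filtering and referencing are linear", {
  set.seed(7)
  a <- make_recording(matrix(rnorm(2 * 5000), 2), rate = 1000)
  b <- make_recording(matrix(rnorm(2 * 5000), 2), rate = 1000)
  ab <- make_recording(a$data + b$data, rate = 1000)
  expect_equal(bandpass_notch(ab)$data,
               bandpass_notch(a)$data + bandpass_notch(b)$data,
               tolerance = 1e-10)
})

test_that("resampling halves the sample count and preserves signals", {
  tt <- (0:9999) / 1000
  rec <- make_recording(matrix(sin(2 * pi * 20 * tt), 1), rate = 1000,
                        onsets = 2.0)
  out <- resample_recording(rec, 500)
  expect_equal(ncol(out$data), 5000)
  expect_equal(out$rate, 500)
  # 20 Hz amplitude preserved within 2% (away from the ends)
  expect_equal(rms(out$data[1, 1000:4000]) / rms(rec$data[1, 2000:8000]), 1,
               tolerance = 0.02)
  # onset stored in seconds: re-indexing is exact to one output sample
  expect_equal(round(out$onsets * out$rate), 1000)
  expect_error(resample_recording(rec, 2000), "exceed")
})

test_that("onset detection finds first crossings with a refractory period", {
  force <- numeric(20000)
  force[1234:1300] <- 1               # step exceeding threshold at 1234
  expect_equal(detect_onsets(force, 0.5, 1000), 1234L)
  expect_length(detect_onsets(numeric(5000), 0.5, 1000), 0)
  force2 <- numeric(25000)
  force2[3000:3200] <- 1
  force2[13000:13200] <- 1            # 10 s later
  expect_equal(detect_onsets(force2, 0.5, 1000), c(3000L, 13000L))
  # bouncy crossing within the refractory window triggers once
  force3 <- numeric(10000)
  force3[c(1000:1050, 1500:1550)] <- 1
  expect_equal(detect_onsets(force3, 0.5, 1000), 1000L)
  expect_error(detect_onsets(numeric(0), 0.5, 1000), "empty")
})

test_that("epoching obeys its counting and boundary contracts", {
  rec <- make_recording(matrix(rnorm(180 * 500), 1), rate = 500)
  ep <- epoch_recording(rec, "resting")
  expect_equal(dim(ep$data), c(90, 1, 1000))
  # trailing partial segment dropped: floor(duration / 2 s)
  rec2 <- make_recording(matrix(0, 1, 2999), rate = 500)
  expect_equal(dim(epoch_recording(rec2, "resting")$data)[1L], 2)
  expect_error(epoch_recording(make_recording(matrix(0, 1, 500), rate = 500),
                               "resting"), "shorter")
  # event epochs need the full -2500..4500 ms inside the recording
  rec3 <- make_recording(matrix(0, 1, 10 * 500), rate = 500)
  expect_error(epoch_recording(rec3, "event", onsets = 500), "complete epoch")
  ep3 <- epoch_recording(rec3, "event", onsets = c(500, 1500, 2000))
  expect_equal(dim(ep3$data), c(2, 1, 3500))
  expect_equal(ep3$t0, -2500)
  # one epoch per valid onset
  rec4 <- make_recording(matrix(0, 1, 610 * 500), rate = 500,
                         onsets = 5 + (0:59) * 10)
  expect_equal(dim(epoch_recording(rec4, "event")$data)[1L], 60)
})

test_that("rejection flags bursts, referencing zeroes the channel mean", {
  set.seed(1)
  data <- array(rnorm(30 * 4 * 200, sd = 10), c(30, 4, 200))
  data[17, 2, 50:60] <- data[17, 2, 50:60] + 500   # 10x amplitude burst
  ep <- make_epochs(data)
  out <- reject_and_reference(ep, ptp_limit = 200, min_trials = 5)
  expect_equal(which(out$rejected), 17L)
  expect_match(out$reject_reason[17], "ptp")
  # cross-channel mean is zero at every sample after referencing
  cm <- apply(out$data, c(1, 3), mean)
  expect_lt(max(abs(cm)), 1e-9)
  # idempotent: second pass changes nothing
  out2 <- reject_and_reference(out, ptp_limit = 200, min_trials = 5)
  expect_identical(out2$rejected, out$rejected)
  expect_equal(out2$data, out$data)
})

test_that("too few surviving trials raises the exclusion signal", {
  set.seed(2)
  data <- array(rnorm(19 * 3 * 100), c(19, 3, 100))
  ep <- make_epochs(data)
  expect_warning(out <- reject_and_reference(ep, ptp_limit = 1e6,
                                             min_trials = 20),
                 class = "imcoh_participant_excluded")
  expect_true(attr(out, "excluded"))
  expect_equal(attr(out, "n_surviving"), 19L)
  # all-rejected is an error
  expect_error(suppressWarnings(reject_and_reference(ep, ptp_limit = 1e-12)),
               "all trials")
})
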