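fs <- 256

test_that("baseline removal zeroes a constant signal and rejects short ones", {
  x <- matrix(7.5, 2, 4 * fs)
  rec <- eeg_recording(x, fs, c("A", "B"), "resting")
  out <- remove_baseline(rec)
  expect_equal(out$data, rec$data * 0)
  short <- eeg_recording(matrix(1, 1, 30), fs, "A", "resting")
  expect_error(remove_baseline(short), "shorter")
})

test_that("baseline removal kills slow drift and keeps a 10 Hz tone", {
  t <- seq_len(20 * fs) / fs
  drift <- 100 * sin(2 * pi * 0.1 * t)
  tone <- 10 * sin(2 * pi * 10 * t)
  rec <- eeg_recording(matrix(drift + tone, 1), fs, "A", "resting")
  out <- remove_baseline(rec)
  att <- periodogram_band(out$data[1, ], fs, 0.05, 0.3) /
    periodogram_band(drift + tone, fs, 0.05, 0.3)
  expect_lt(10 * log10(att), -20)
  amp10 <- function(x) {
    n <- length(x); 2 * abs(stats::fft(x))[round(10 * n / fs) + 1] / n
  }
  expect_lt(abs(amp10(out$data[1, ]) / amp10(drift + tone) - 1), 0.05)
})

test_that("band-reject notch meets its attenuation and ripple contract", {
  cfg <- filter_config()
  b <- qeegtova:::design_notch(cfg, fs)
  f <- seq(0.5, 127.5, by = 0.25)
  H <- vapply(f, function(fr)
    abs(sum(b * exp(-2i * pi * fr * (seq_along(b) - 1) / fs))), numeric(1))
  expect_lt(20 * log10(H[f == 60]), -40)
  passband <- f < 60 - 3 * cfg$notch_halfwidth | f > 60 + 3 * cfg$notch_halfwidth
  expect_lt(max(abs(20 * log10(H[passband]))), 1)
})

test_that("remove_line attenuates 60 Hz, preserves 10 Hz, passes zeros", {
  t <- seq_len(8 * fs) / fs
  rec <- eeg_recording(rbind(sin(2 * pi * 60 * t + 0.7),
                             sin(2 * pi * 10 * t + 0.2),
                             rep(0, length(t))),
                       fs, c("A", "B", "C"), "resting")
  out <- remove_line(rec)
  expect_lt(sd(out$data[1, ]) / sd(rec$data[1, ]), 0.01)
  expect_lt(abs(20 * log10(sd(out$data[2, ]) / sd(rec$data[2, ]))), 1)
  expect_equal(out$data[3, ], rec$data[3, ])
  # notch above Nyquist rejected
  low_fs <- eeg_recording(matrix(rnorm(600), 1), 100, "A", "resting")
  expect_error(remove_line(low_fs), "Nyquist")
})

test_that("EOG removal cancels injected blinks and passes through clean data", {
  spec <- cohort_spec(fs = fs, rest_duration = 60,
                      control = control_profile(blink_rate = 20,
                                                drift_amplitude = 0,
                                                line_amplitude = 0))
  rec <- simulate_recording(NULL, spec$control, spec, seed = 5)
  blink <- rec$aux$blink
  raw_cor <- abs(cor(rec$data["Fp1", ], blink))
  expect_gte(raw_cor, 0.8)
  cleaned <- remove_eog(rec)
  expect_true(attr(cleaned, "eog_removed"))
  post_cor <- max(abs(apply(cleaned$data, 1, cor, y = blink)))
  expect_lte(post_cor, 0.2)
  # blink-free input is returned unchanged
  spec0 <- cohort_spec(fs = fs, rest_duration = 60,
                       control = control_profile(blink_rate = 0,
                                                 drift_amplitude = 0,
                                                 line_amplitude = 0))
  rec0 <- simulate_recording(NULL, spec0$control, spec0, seed = 6)
  out0 <- remove_eog(rec0)
  expect_false(attr(out0, "eog_removed"))
  expect_lt(sd(out0$data - rec0$data) / sd(rec0$data), 0.05)
})

test_that("EOG removal preconditions: duration and channel presence", {
  short <- eeg_recording(matrix(rnorm(19 * 10 * fs), 19), fs,
                         tova_montage(), "resting")
  expect_error(remove_eog(short), "30 s")
  few <- eeg_recording(matrix(rnorm(3 * 40 * fs), 3), fs,
                       c("Fp1", "Fp2", "F7"), "resting")
  expect_error(remove_eog(few), "F8")
})

test_that("preprocessing preserves shape, labels, fs and ordering", {
  spec <- cohort_spec(fs = fs, rest_duration = 40)
  rec <- simulate_recording(NULL, spec$control, spec, seed = 2)
  out <- preprocess(rec)
  expect_identical(dim(out$data), dim(rec$data))
  expect_identical(out$labels, rec$labels)
  expect_identical(out$fs, rec$fs)
  expect_identical(out$state_tag, rec$state_tag)
})

test_that("full chain keeps summed 4-16 Hz power within 15% on clean input", {
  spec <- cohort_spec(fs = fs, rest_duration = 60,
                      control = control_profile(blink_rate = 0,
                                                drift_amplitude = 0,
                                                line_amplitude = 0))
  rec <- simulate_recording(NULL, spec$control, spec, seed = 9)
  cl <- preprocess(rec)
  before <- apply(rec$data, 1, periodogram_band, fs = fs, lo = 4, hi = 16)
  after <- apply(cl$data, 1, periodogram_band, fs = fs, lo = 4, hi = 16)
  expect_lt(max(abs(after / before - 1)), 0.15)
  # individual bands drift more (the median cascade's |1-H| lobes); bounded
  for (band in qeeg_bands()[c("theta", "alpha", "beta")]) {
    b0 <- apply(rec$data, 1, periodogram_band, fs = fs, lo = band[1], hi = band[2])
    b1 <- apply(cl$data, 1, periodogram_band, fs = fs, lo = band[1], hi = band[2])
    expect_lt(max(abs(b1 / b0 - 1)), 0.30)
  }
  # the 0.2 s median window necessarily bites into the delta band
  d0 <- apply(rec$data, 1, periodogram_band, fs = fs, lo = 1, hi = 4)
  d1 <- apply(cl$data, 1, periodogram_band, fs = fs, lo = 1, hi = 4)
  expect_lt(mean(d1 / d0), 0.5)
  # reapplication perturbs the passband by a bounded amount (the nonlinear
  # median cascade is not exactly idempotent)
  cl2 <- preprocess(cl)
  b1 <- apply(cl$data, 1, periodogram_band, fs = fs, lo = 4, hi = 16)
  b2 <- apply(cl2$data, 1, periodogram_band, fs = fs, lo = 4, hi = 16)
  expect_lt(max(abs(b2 / b1 - 1)), 0.25)
})
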